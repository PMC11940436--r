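spectralRadius <- function(W) {
  n <- nrow(W)
  if (n <= 1500L) {
    max(Mod(eigen(as.matrix(W), only.values = TRUE)$values))
  } else {
    # power iteration on W'W via normalised repeated application
    v <- rep(1 / sqrt(n), n)
    est <- 0
    for (i in seq_len(200L)) {
      v2 <- as.numeric(W %*% v)
      nrm <- sqrt(sum(v2^2))
      if (nrm == 0) return(0)
      v <- v2 / nrm
      if (abs(nrm - est) < 1e-10 * max(nrm, 1)) break
      est <- nrm
    }
    est
  }
}

#' Create a readout head
#'
#' @param nOutputs output dimension.
#' @param d input dimension (reservoir size + input size).
#' @param epsilon RLS regularisation; `P` starts at `I / epsilon`.
#' @param forgetting RLS forgetting factor in (0, 1].
#' @param alpha reinforcement learning rate.
#' @param delta eligibility-trace decay rate.
#' @return a [ReadoutHead-class].
#' @export
readoutHead <- function(nOutputs, d, epsilon = 1e-2, forgetting = 1,
                        alpha = 1e-3, delta = 0.9) {
  new("ReadoutHead", Wout = matrix(0, nOutputs, d),
      P = diag(d) / epsilon, forgetting = forgetting,
      E = matrix(0, nOutputs, d), alpha = alpha, delta = delta)
}

#' Initialise an Echo State Network
#'
#' `Win` is uniform in `[-inputScale, inputScale]`; `Wres` has exactly
#' `floor(sparsity * N^2)` nonzero entries at random positions, values
#' uniform in `[-1, 1]`, rescaled so its spectral radius equals `rho`
#' (below one, which gives the echo-state property: the reservoir forgets
#' its initial condition). Heads are added with [addHead()].
#'
#' @param N reservoir size.
#' @param K input size.
#' @param a leaking rate in (0, 1].
#' @param sparsity fraction of nonzero reservoir weights in (0, 1].
#' @param rho target spectral radius (< 1).
#' @param inputScale input weight scale.
#' @param seed RNG seed; identical seeds give identical models.
#' @return an [ESNModel-class] with no heads.
#' @export
esnInit <- function(N, K, a = 0.5, sparsity = 0.5, rho = 0.95,
                    inputScale = 1, seed = 1L) {
  if (N < 1L || K < 1L) stop("N and K must be >= 1")
  if (sparsity <= 0 || sparsity > 1) stop("sparsity must be in (0, 1]")
  if (rho >= 1) stop("spectral radius must be below 1")
  if (a <= 0 || a > 1) stop("leaking rate must be in (0, 1]")
  set.seed(as.integer(seed))
  Win <- matrix(stats::runif(N * K, -inputScale, inputScale), N, K)
  nnz <- floor(sparsity * N^2)
  pos <- sample.int(N^2, nnz) - 1L
  W <- Matrix::sparseMatrix(i = (pos %% N) + 1L, j = (pos %/% N) + 1L,
                            x = stats::runif(nnz, -1, 1), dims = c(N, N))
  sr <- spectralRadius(W)
  if (sr > 0) W <- W * (rho / sr)
  new("ESNModel", Win = Win, Wres = as(W, "CsparseMatrix"), a = a,
      R = rep(0, N), heads = list(), rho = rho)
}

#' @rdname esnInit
#' @param model an [ESNModel-class].
#' @param name head name (`"state"`, `"trajectory"`, `"satisfaction"`).
#' @param nOutputs head output dimension.
#' @param ... passed to [readoutHead()].
#' @export
addHead <- function(model, name, nOutputs, ...) {
  d <- nrow(model@Win) + ncol(model@Win)
  model@heads[[name]] <- readoutHead(nOutputs, d, ...)
  model
}

#' One reservoir update step
#'
#' \deqn{R(t) = (1-a) R(t-1) + a \tanh(W_{in} in(t) + W_{res} R(t-1))}
#'
#' @param model an [ESNModel-class].
#' @param input input vector of length K.
#' @return the model with updated reservoir state `R`.
#' @export
esnStep <- function(model, input) {
  if (length(input) != ncol(model@Win))
    stop("input has length ", length(input), ", expected ", ncol(model@Win))
  pre <- as.numeric(model@Win %*% input) + as.numeric(model@Wres %*% model@R)
  model@R <- (1 - model@a) * model@R + model@a * tanh(pre)
  model
}

#' Linear readout of one head
#'
#' `out = Wout %*% c(R, in)`: a linear combination of the concatenated
#' reservoir state and current input.
#'
#' @param model an [ESNModel-class] whose `R` is current.
#' @param head head name.
#' @param input the current input vector (length K).
#' @return numeric output vector.
#' @export
esnOutput <- function(model, head, input) {
  h <- model@heads[[head]]
  if (is.null(h)) stop("unknown head: ", head)
  as.numeric(h@Wout %*% c(model@R, input))
}

#' Recursive-least-squares update of a readout head
#'
#' Standard RLS with forgetting: `g = P x / (lambda + x' P x)`;
#' `P <- (P - g x' P) / lambda`; `Wout <- Wout + (target - Wout x) g'`.
#' With `forgetting = 1` and `P0 = I / epsilon` this converges to the
#' batch ridge solution with penalty `epsilon`.
#'
#' @param head a [ReadoutHead-class].
#' @param x concatenated vector `c(R, in)`.
#' @param target desired output vector.
#' @return the updated head.
#' @export
rlsUpdate <- function(head, x, target) {
  if (!all(is.finite(x)) || !all(is.finite(target)))
    stop("non-finite values in RLS update")
  if (length(x) != ncol(head@Wout) || length(target) != nrow(head@Wout))
    stop("dimension mismatch in RLS update")
  Px <- as.numeric(head@P %*% x)
  denom <- head@forgetting + sum(x * Px)
  g <- Px / denom
  head@P <- (head@P - tcrossprod(g, Px)) / head@forgetting
  err <- target - as.numeric(head@Wout %*% x)
  head@Wout <- head@Wout + tcrossprod(err, g)
  head
}

#' Satisfaction-gated reinforcement update of a readout head
#'
#' Eligibility trace and weight update:
#' \deqn{E \leftarrow \delta E + (1-\delta)\, out \otimes [R; in]}
#' \deqn{W_{out} \leftarrow W_{out} - \alpha (1 - satisfaction) E}
#' With `satisfaction = 1` the weights are untouched (the trace still
#' accumulates); with dissatisfaction the recently eligible weight-output
#' products are suppressed.
#'
#' @param head a [ReadoutHead-class].
#' @param x concatenated vector `c(R, in)`.
#' @param out the predicted output vector at `x`.
#' @param satisfaction 0 (dissatisfied) or 1 (satisfied).
#' @return the updated head.
#' @export
rlUpdate <- function(head, x, out, satisfaction) {
  if (!satisfaction %in% c(0, 1)) stop("satisfaction must be 0 or 1")
  if (length(x) != ncol(head@Wout) || length(out) != nrow(head@Wout))
    stop("dimension mismatch in RL update")
  head@E <- head@delta * head@E + (1 - head@delta) * tcrossprod(out, x)
  head@Wout <- head@Wout - head@alpha * (1 - satisfaction) * head@E
  head
}

#' Decode a categorical output by argmax
#'
#' Ties are broken toward the lowest index.
#'
#' @param scores numeric score vector over classes.
#' @return 1-based class index.
#' @export
decodeState <- function(scores) {
  if (length(scores) == 0L) stop("empty score vector")
  which.max(scores)
}

#' Decode the binary satisfaction output
#'
#' @param scores length-2 score vector (dissatisfied, satisfied).
#' @return 0 or 1.
#' @export
decodeSatisfaction <- function(scores) {
  if (length(scores) != 2L) stop("satisfaction scores must have length 2")
  decodeState(scores) - 1L
}

setMethod("show", "ESNModel", function(object) {
  cat(sprintf("ESNModel: N = %d, K = %d, a = %.2f, rho = %.3g, %d nonzeros\n",
              nrow(object@Win), ncol(object@Win), object@a, object@rho,
              Matrix::nnzero(object@Wres)))
  for (nm in names(object@heads))
    cat(sprintf("  head '%s': %d outputs\n", nm,
                nrow(object@heads[[nm]]@Wout)))
  invisible(NULL)
})
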