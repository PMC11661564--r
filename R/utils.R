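#' Inverse logit
#'
#' @param x numeric vector of linear predictors.
#' @return `exp(x) / (1 + exp(x))`, computed stably.
#' @keywords internal
expit <- function(x) stats::plogis(x)

# logit with probability floor; used before fluctuation offsets
logit_bounded <- function(p, eps = 1e-8) {
  stats::qlogis(pmin(pmax(p, eps), 1 - eps))
}

# derive a child seed (< 2^31) from a master seed and an index
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + as.double(index) * 16807) %% 2147483587L) + 1L
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# fast design builder: terms is a character vector of column names of `frame`
# (fast path, intercept prepended) or a one-sided formula (general path).
build_design <- function(frame, terms) {
  if (inherits(terms, "formula")) {
    return(stats::model.matrix(terms, data = frame))
  }
  if (length(terms) == 0L) {
    return(matrix(1, nrow(frame), 1L, dimnames = list(NULL, "(Intercept)")))
  }
  X <- as.matrix(frame[terms])
  storage.mode(X) <- "double"
  cbind("(Intercept)" = 1, X)
}
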