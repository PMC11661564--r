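#' Longitudinal panels and the augmented (window-stacked) dataset
#'
#' A longitudinal panel is a long-format data frame with one row per
#' individual and time point, holding a binary treatment `A`, a binary
#' censoring indicator `C`, a binary absorbing outcome `Y`, time-varying
#' covariates and baseline covariates. [build_augmented()] rearranges a panel
#' into the stacked window-level dataset on which every estimator in the
#' package operates: one row per individual and window of `s` consecutive
#' treatment times, with the outcome read at the window end.
#'
#' Conventions: time is 1-based and consecutive within an individual; the
#' baseline outcome is `Y = 0` at `t = 1` for everyone; the outcome is
#' absorbing; censoring is absorbing and hides all subsequent treatment,
#' covariate and outcome values. Within a window, an event occurring during
#' the exposure follow-up (strictly after the window start and before the
#' window-end outcome time) is coded as censoring from that time on, so that
#' trajectory groups are only formed from exposure histories that were
#' actually at risk; the event still propagates to the window-end outcome.
#'
#' @name panel
NULL

#' Validate and tag a long-format longitudinal panel
#'
#' @param data data frame with columns `id`, `t`, `A`, `C`, `Y`, plus
#'   time-varying covariate columns and baseline covariate columns.
#' @param tv_covariates character vector of time-varying covariate column
#'   names (default: `"L"` if present, otherwise none).
#' @param baseline character vector of baseline covariate column names
#'   (default: `"V"` if present, otherwise none). Baseline values must be
#'   constant within an individual.
#' @return the data frame, ordered by `(id, t)`, with class
#'   `"hrmsm_panel"` and attributes `tv_covariates` and `baseline`.
#' @export
as_longitudinal_panel <- function(data, tv_covariates = NULL, baseline = NULL) {
  data <- as.data.frame(data)
  need <- c("id", "t", "A", "C", "Y")
  miss <- setdiff(need, names(data))
  if (length(miss)) stop("panel is missing columns: ", paste(miss, collapse = ", "))
  if (is.null(tv_covariates)) tv_covariates <- intersect("L", names(data))
  if (is.null(baseline)) baseline <- intersect("V", names(data))
  data <- data[order(data$id, data$t), , drop = FALSE]
  rownames(data) <- NULL

  sp <- split(seq_len(nrow(data)), data$id)
  for (idx in sp) {
    tt <- data$t[idx]
    if (!identical(as.integer(tt), seq_len(length(tt))))
      stop("times within an individual must be consecutive integers starting at 1 (id ",
           data$id[idx[1]], ")")
  }
  if (any(data$Y[data$t == 1] != 0, na.rm = TRUE))
    stop("baseline outcome must be Y = 0 at t = 1 for every individual")
  y_ok <- tapply(data$Y, data$id, function(y) {
    y <- y[!is.na(y)]
    all(diff(y) >= 0)
  })
  if (!all(unlist(y_ok))) stop("Y must be absorbing: once 1, it stays 1")
  for (v in baseline) {
    n_v <- tapply(data[[v]], data$id, function(x) length(unique(x[!is.na(x)])))
    if (any(unlist(n_v) > 1)) stop("baseline covariate ", v, " varies within an individual")
  }
  structure(data, class = c("hrmsm_panel", "data.frame"),
            tv_covariates = tv_covariates, baseline = baseline)
}

#' Number of sliding windows of length s over K treatment times
#'
#' @param K total number of treatment times.
#' @param s window length (history size), `1 <= s <= K`.
#' @return `K - s + 1`.
#' @examples
#' count_windows(60, 6) # 55 overlapping windows
#' @export
count_windows <- function(K, s) {
  K <- as.integer(K); s <- as.integer(s)
  if (s < 1L) stop("s must be >= 1")
  if (s > K) stop("s (", s, ") exceeds the number of treatment times K (", K, ")")
  K - s + 1L
}

#' Enumerate all deterministic treatment regimes of length s
#'
#' @param s window length.
#' @return a `2^s` x `s` integer matrix, one regime per row, in
#'   lexicographic order (first column varies slowest).
#' @export
enumerate_regimes <- function(s) {
  s <- as.integer(s)
  if (s < 1L) stop("s must be >= 1")
  m <- as.matrix(rev(expand.grid(rev(lapply(seq_len(s), function(i) 0:1)))))
  m <- m[, seq_len(s), drop = FALSE]
  dimnames(m) <- list(apply(m, 1, paste, collapse = ""), paste0("a", seq_len(s)))
  storage.mode(m) <- "integer"
  m
}

# wide layout of a panel: one row per id, columns V..., A.t, C.t, L.t, Y.t
panel_wide <- function(panel) {
  tv <- attr(panel, "tv_covariates")
  bl <- attr(panel, "baseline")
  ids <- unique(panel$id)
  Tmax <- max(panel$t)
  n <- length(ids)
  wide <- data.frame(id = ids)
  row_of <- match(panel$id, ids)
  for (v in bl) {
    x <- rep(NA_real_, n)
    x[row_of[panel$t == 1]] <- panel[[v]][panel$t == 1]
    wide[[v]] <- x
  }
  for (v in c("A", "C", "Y", tv)) {
    for (tt in seq_len(Tmax)) {
      sel <- panel$t == tt
      x <- rep(NA_real_, n)
      x[row_of[sel]] <- panel[[v]][sel]
      wide[[paste0(v, ".", tt)]] <- x
    }
  }
  attr(wide, "Tmax") <- Tmax
  attr(wide, "tv_covariates") <- tv
  attr(wide, "baseline") <- bl
  wide
}

#' Build the augmented window-stacked dataset
#'
#' Rearranges a longitudinal panel into `D` overlapping windows of `s`
#' treatment times, window `d` covering times `d .. d+s-1` with the outcome
#' read at `d + s`. `D` is the number of windows for which the window-end
#' outcome exists in the data. Each individual contributes at most one row
#' per window; only individuals event-free at the window start (`Y_d = 0`)
#' are at risk. Events during the exposure follow-up are coded as censoring
#' from the event time on (the window-end outcome is still propagated as 1).
#'
#' @param panel an [as_longitudinal_panel()] object (plain data frames are
#'   coerced).
#' @param s window length (number of treatment times per window).
#' @return an object of class `"hrmsm_aug"`: a list with `data` (one row per
#'   id and window: `id`, `d`, `at_risk`, `complete`, `y_end`, `a1..as`,
#'   `c1..cs`, `reason`), the wide panel (`wide`), `s`, `D`, `n_d` (at-risk
#'   count per window) and covariate name metadata.
#' @export
build_augmented <- function(panel, s) {
  if (!inherits(panel, "hrmsm_panel")) panel <- as_longitudinal_panel(panel)
  s <- as.integer(s)
  wide <- panel_wide(panel)
  Tmax <- attr(wide, "Tmax")
  # last usable outcome time: largest t with any Y observed
  yobs <- vapply(seq_len(Tmax), function(tt) any(!is.na(wide[[paste0("Y.", tt)]])), TRUE)
  K_Y <- max(which(yobs))
  D <- K_Y - s
  if (s < 1L) stop("s must be >= 1")
  if (D < 1L)
    stop("window length s = ", s, " leaves no complete window; the maximum feasible s is ",
         K_Y - 1L)
  n <- nrow(wide)
  rows <- vector("list", D)
  for (d in seq_len(D)) {
    jj <- d:(d + s - 1L)
    Yd <- if (d == 1L) rep(0, n) else wide[[paste0("Y.", d)]]
    at_risk <- !is.na(Yd) & Yd == 0
    A <- as.matrix(wide[paste0("A.", jj)])
    C <- as.matrix(wide[paste0("C.", jj)])
    Ywin <- as.matrix(wide[paste0("Y.", jj)])
    y_end <- wide[[paste0("Y.", d + s)]]
    cseq <- matrix(0L, n, s)
    reason <- rep("none", n)
    for (k in seq_len(s)) {
      tt <- jj[k]
      ltfu <- !is.na(C[, k]) & C[, k] == 1
      event <- tt > d & !is.na(Ywin[, k]) & Ywin[, k] == 1
      new_c <- (ltfu | event) & (if (k == 1L) TRUE else cseq[, k - 1L] == 0L)
      cseq[, k] <- if (k == 1L) as.integer(ltfu | event) else pmax(cseq[, k - 1L], as.integer(ltfu | event))
      reason[new_c & event] <- "event"
      reason[new_c & ltfu & !event] <- "ltfu"
      # once censored (or panel-missing) the treatment is missing
      A[cseq[, k] == 1L, k] <- NA_real_
    }
    complete <- rowSums(cseq) == 0L & !apply(A, 1, anyNA)
    y_out <- ifelse(complete, y_end, ifelse(reason == "event", 1, NA_real_))
    df <- data.frame(id = wide$id, d = d, wrow = seq_len(n),
                     at_risk = at_risk, complete = complete & at_risk,
                     y_end = y_out, reason = reason,
                     stringsAsFactors = FALSE)
    colnames(A) <- paste0("a", seq_len(s))
    colnames(cseq) <- paste0("c", seq_len(s))
    rows[[d]] <- cbind(df, as.data.frame(A), as.data.frame(cseq))
  }
  data <- do.call(rbind, rows)
  data <- data[data$at_risk, , drop = FALSE]
  rownames(data) <- NULL
  n_d <- as.integer(table(factor(data$d, levels = seq_len(D))))
  structure(list(data = data, wide = wide, s = s, D = D, n = n, n_d = n_d,
                 tv_covariates = attr(wide, "tv_covariates"),
                 baseline = attr(wide, "baseline")),
            class = "hrmsm_aug")
}

#' @export
print.hrmsm_aug <- function(x, ...) {
  cat("Augmented window dataset: ", x$n, " individuals, s = ", x$s,
      ", D = ", x$D, " window(s)\n", sep = "")
  cat("At-risk rows per window: ", paste(x$n_d, collapse = ", "), "\n", sep = "")
  cmpl <- tapply(x$data$complete, x$data$d, sum)
  cat("Complete (uncensored) rows per window: ", paste(cmpl, collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Read / write long-format panels and augmented data as CSV
#'
#' Missing values are written as empty fields.
#'
#' @param file path to a CSV file.
#' @param ... passed to [as_longitudinal_panel()] (e.g. `tv_covariates`).
#' @return `read_panel()` returns an `hrmsm_panel`.
#' @export
read_panel <- function(file, ...) {
  df <- utils::read.csv(file, na.strings = "")
  as_longitudinal_panel(df, ...)
}

#' @rdname read_panel
#' @param panel a longitudinal panel.
#' @export
write_panel <- function(panel, file) {
  utils::write.csv(as.data.frame(panel), file, row.names = FALSE, na = "")
  invisible(file)
}

#' @rdname read_panel
#' @param aug an `hrmsm_aug` object.
#' @export
write_augmented <- function(aug, file) {
  d <- aug$data
  s <- aug$s
  long <- do.call(rbind, lapply(seq_len(s), function(k) {
    data.frame(id = d$id, d = d$d, j = d$d + k - 1L,
               A_j = d[[paste0("a", k)]], C_j = d[[paste0("c", k)]],
               Y_end = d$y_end, at_risk = as.integer(d$at_risk),
               complete = as.integer(d$complete))
  }))
  long <- long[order(long$id, long$d, long$j), ]
  utils::write.csv(long, file, row.names = FALSE, na = "")
  invisible(file)
}

# observed within-window regime string for complete rows; NA otherwise
observed_regime <- function(aug) {
  a <- as.matrix(aug$data[paste0("a", seq_len(aug$s))])
  key <- apply(a, 1, function(r) if (anyNA(r)) NA_character_ else paste(r, collapse = ""))
  key
}
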