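#' Multiple imputation by predictive mean matching
#'
#' Hot-deck imputation of missing numeric cells: for each target column, the
#' observed values are regressed on the predictors; for each imputed copy a
#' Bayesian draw of the regression parameters predicts every row, the `k`
#' observed rows whose (least-squares) predictions are closest to the missing
#' row's (parameter-draw) prediction form the donor pool, and one donor's
#' observed value is copied at random. Imputed values are therefore always
#' members of the observed values of their column. Sample-size-like columns can
#' be imputed on the log scale and rounded to integers >= 2 via `integer_cols`.
#'
#' @param table data frame.
#' @param targets names of columns to impute.
#' @param predictors names of numeric predictor columns (complete, or at least
#'   observed wherever needed; rows with missing predictors fall back to the
#'   column mean prediction).
#' @param m number of completed copies (default 20).
#' @param k donor-pool size (default 5); shrunk with a warning when fewer
#'   donors exist.
#' @param integer_cols subset of `targets` modelled on the log scale and
#'   rounded to integers >= 2 (sample sizes).
#' @param seed integer seed.
#' @return list of class `"pmm_imputation"`: `imputations` (list of `m`
#'   completed data frames), `cells` (data frame of imputed row/column pairs),
#'   `m`, `k`, `seed`.
#' @export
pmm_impute <- function(table, targets, predictors, m = 20L, k = 5L,
                       integer_cols = character(), seed = NULL) {
  stopifnot(m >= 1L, k >= 1L)
  if (!is.null(seed)) set.seed(seed)
  for (cn in c(targets, predictors))
    if (!cn %in% names(table)) stop("no column '", cn, "'")
  cells <- do.call(rbind, lapply(targets, function(cn) {
    i <- which(is.na(table[[cn]]))
    if (length(i)) data.frame(row = i, column = cn) else NULL
  }))
  copies <- lapply(seq_len(m), function(j) table)
  if (is.null(cells)) {
    return(structure(list(imputations = copies, cells = data.frame(),
                          m = m, k = k, seed = seed),
                     class = "pmm_imputation"))
  }
  X <- as.matrix(cbind(`(Intercept)` = 1,
                       table[, predictors, drop = FALSE]))
  storage.mode(X) <- "double"
  # rows with any missing predictor predict from the intercept only
  badp <- rowSums(is.na(X)) > 0L
  X[is.na(X)] <- 0

  for (cn in targets) {
    mis <- is.na(table[[cn]])
    if (!any(mis)) next
    if (all(mis)) stop("column '", cn, "' has no observed values")
    y <- table[[cn]]
    logscale <- cn %in% integer_cols
    if (logscale) y <- log(y)
    oi <- which(!mis)
    kk <- k
    if (length(oi) < k + 1L) {
      kk <- max(1L, length(oi) - 1L)
      warning("column '", cn, "': donor pool shrunk to ", kk)
    }
    Xo <- X[oi, , drop = FALSE]
    Xo[badp[oi], -1L] <- 0
    yo <- y[oi]
    XtX <- crossprod(Xo) + diag(1e-8, ncol(Xo))
    bh <- solve(XtX, crossprod(Xo, yo))
    yhat_obs <- as.vector(Xo %*% bh)
    res <- yo - yhat_obs
    df <- max(length(oi) - ncol(Xo), 1L)
    for (j in seq_len(m)) {
      # Bayesian parameter draw so copies differ (sigma^2 ~ scaled inv-chi2)
      s2 <- sum(res^2) / stats::rchisq(1L, df)
      bstar <- bh + drop(chol_psd(s2 * solve(XtX)) %*%
                           stats::rnorm(ncol(Xo)))
      Xm <- X[mis, , drop = FALSE]
      Xm[badp[mis], -1L] <- 0
      yhat_mis <- as.vector(Xm %*% bstar)
      for (ii in seq_along(yhat_mis)) {
        d <- abs(yhat_obs - yhat_mis[ii])
        donors <- oi[order(d)[seq_len(kk)]]
        val <- table[[cn]][donors[sample.int(kk, 1L)]]
        if (cn %in% integer_cols) val <- max(2L, as.integer(round(val)))
        copies[[j]][[cn]][which(mis)[ii]] <- val
      }
    }
  }
  structure(list(imputations = copies, cells = cells, m = m, k = k,
                 seed = seed), class = "pmm_imputation")
}

#' @export
print.pmm_imputation <- function(x, ...) {
  cat("Predictive-mean-matching imputation: m =", x$m, ", k =", x$k,
      ",", nrow(x$cells), "cell(s) imputed\n")
  invisible(x)
}
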