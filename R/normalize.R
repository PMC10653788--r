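#' Voom-style log-CPM transform with precision weights
#'
#' Transforms a sample x genus count matrix to
#' `log2((count + pseudocount) / (library_size + 2 * pseudocount) * cpm_scale)`
#' and fits a mean-variance trend (lowess of the square-root residual SD
#' against the mean log-count, per genus) from which per-observation
#' precision weights are derived. The transform is finite for zero counts.
#'
#' @param counts Non-negative integer matrix, samples in rows, genera in
#'   columns, dimnames set.
#' @param lib_size Optional numeric vector of library sizes (one per
#'   sample), e.g. total sequencing depth. Defaults to row sums of
#'   `counts`; zero row sums without an override are an error.
#' @param pseudocount Offset added to counts (default 0.5).
#' @param cpm_scale Counts-per-million scale factor (default 1e6).
#' @param lowess_span Smoother span for the mean-variance trend, in (0, 1].
#' @return A list of class `normalized_matrix` with elements `values`
#'   (real matrix, same dimensions and dimnames as `counts`), `weights`
#'   (precision weights, same shape), `mode` (`"voom"` until an SNM step
#'   sets it), `lib_size`, and `params`.
#' @export
voom_transform <- function(counts, lib_size = NULL, pseudocount = 0.5,
                           cpm_scale = 1e6, lowess_span = 0.5) {
  stopifnot(is.matrix(counts), is.numeric(counts))
  check_scalar(pseudocount, "pseudocount", .Machine$double.eps)
  check_scalar(lowess_span, "lowess_span", .Machine$double.eps, 1)
  if (is.null(lib_size)) {
    lib_size <- rowSums(counts)
    if (any(lib_size == 0)) {
      stop("some samples have zero library size; supply 'lib_size'",
           call. = FALSE)
    }
  } else {
    stopifnot(length(lib_size) == nrow(counts), all(lib_size > 0))
  }

  values <- log2((counts + pseudocount) /
                   (lib_size + 2 * pseudocount) * cpm_scale)

  # gene-level mean-variance trend: sqrt residual SD vs mean log-count
  mean_log <- colMeans(values)
  sd_col <- apply(values, 2, stats::sd)
  ok <- !is.na(sd_col) & sd_col > 0
  weights <- matrix(1, nrow(counts), ncol(counts),
                    dimnames = dimnames(counts))
  if (sum(ok) >= 3) {
    lo <- stats::lowess(mean_log[ok], sqrt(sd_col[ok]), f = lowess_span)
    pred <- stats::approx(lo$x, lo$y, xout = mean_log, rule = 2,
                          ties = mean)$y
    pred <- pmax(pred, 1e-4)
    w_col <- 1 / pred^4
    weights <- matrix(rep(w_col, each = nrow(counts)), nrow(counts),
                      ncol(counts), dimnames = dimnames(counts))
  }

  structure(
    list(values = values, weights = weights, mode = "voom",
         lib_size = lib_size,
         params = list(pseudocount = pseudocount, cpm_scale = cpm_scale,
                       lowess_span = lowess_span),
         bio_vars = character(0), adj_vars = character(0)),
    class = "normalized_matrix"
  )
}

# Build a model matrix (no intercept column collision) from metadata fields.
design_from_meta <- function(meta, vars) {
  if (length(vars) == 0) return(NULL)
  missing <- setdiff(vars, names(meta))
  if (length(missing) > 0) {
    stop("unknown metadata field(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  f <- stats::as.formula(paste("~", paste(vars, collapse = " + ")))
  stats::model.matrix(f, data = meta)[, -1, drop = FALSE]
}

#' SNM-style normalization with an explicit supervised or blind mode
#'
#' Per genus, fits a linear model of the voom-transformed values on
#' "biological" variables (retained) and "adjustment" variables (removed),
#' and returns the values minus the fitted adjustment terms.
#'
#' In **supervised** mode the biological variables (typically including the
#' class label) are fitted *first*; the adjustment model is then fitted on
#' the residuals and only its fitted values are subtracted. Variation that
#' biological and adjustment variables could both explain is therefore
#' credited to the biological side and retained. This is the documented
#' leak mechanism: when class label correlates with library size, genera
#' with all-zero raw counts - whose transformed values are a function of
#' library size alone - come out carrying class-dependent constants.
#'
#' In **blind** mode the class label must not appear in `bio_vars`; with no
#' biological variables the adjustment model is fitted directly to the
#' values, so for an all-zero genus whose transformed value lies exactly in
#' the span of the adjustment covariates the removal is exact and the
#' output is constant. Blind output is invariant to permuting class labels.
#'
#' Genus columns are processed independently; a column that is constant is
#' returned unchanged. A rank-deficient combined design is an error naming
#' the confounded variables.
#'
#' @param voomed A `normalized_matrix` from [voom_transform()].
#' @param meta Metadata data.frame aligned to the rows of
#'   `voomed$values`; factors and numeric covariates are both supported.
#'   A numeric covariate `log_lib` equal to
#'   `log2(library_size + 2 * pseudocount)` is added automatically if
#'   requested in `adj_vars` and absent from `meta`.
#' @param bio_vars Character vector of metadata fields to retain.
#' @param adj_vars Character vector of metadata fields to remove.
#' @param mode `"supervised"` or `"blind"`.
#' @param class_var Name of the class-label field (used to police blind
#'   mode). Default `"class"`.
#' @return A `normalized_matrix` with updated `values`, `mode`,
#'   `bio_vars`, `adj_vars`.
#' @export
snm_normalize <- function(voomed, meta, bio_vars = character(0),
                          adj_vars = character(0),
                          mode = c("supervised", "blind"),
                          class_var = "class") {
  stopifnot(inherits(voomed, "normalized_matrix"))
  mode <- match.arg(mode)
  y <- voomed$values
  stopifnot(nrow(meta) == nrow(y))
  if (mode == "blind" && class_var %in% bio_vars) {
    stop("blind mode must not include the class label '", class_var,
         "' in 'bio_vars'", call. = FALSE)
  }
  if ("log_lib" %in% adj_vars && !("log_lib" %in% names(meta))) {
    meta$log_lib <- log2(voomed$lib_size + 2 * voomed$params$pseudocount)
  }

  x_bio <- design_from_meta(meta, bio_vars)
  x_adj <- design_from_meta(meta, adj_vars)

  # rank check on the combined design
  x_all <- cbind(`(Intercept)` = 1, x_bio, x_adj)
  qr_all <- qr(x_all)
  if (qr_all$rank < ncol(x_all)) {
    dropped <- colnames(x_all)[qr_all$pivot[-seq_len(qr_all$rank)]]
    stop("rank-deficient design; confounded term(s): ",
         paste(dropped, collapse = ", "), call. = FALSE)
  }

  const <- apply(y, 2, function(col) stats::sd(col) == 0)
  out <- y
  active <- which(!const)
  if (length(active) > 0 && (length(bio_vars) > 0 || length(adj_vars) > 0)) {
    yy <- y[, active, drop = FALSE]
    resid <- yy
    if (!is.null(x_bio)) {
      fit_bio <- stats::lm.fit(cbind(1, x_bio), yy)
      resid <- as.matrix(fit_bio$residuals)
    }
    if (!is.null(x_adj)) {
      fit_adj <- stats::lm.fit(cbind(1, x_adj), resid)
      adj_hat <- as.matrix(fit_adj$fitted.values)
      # subtract only the covariate part, keeping each genus's overall level
      adj_centered <- sweep(adj_hat, 2, colMeans(adj_hat))
      out[, active] <- yy - adj_centered
    } else {
      out[, active] <- yy
    }
  }

  structure(
    list(values = out, weights = voomed$weights, mode = mode,
         lib_size = voomed$lib_size, params = voomed$params,
         bio_vars = bio_vars, adj_vars = adj_vars),
    class = "normalized_matrix"
  )
}
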