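#' Assemble the per-gene feature table
#'
#' Joins the methylome summary, the per-gene transmit-type counts, the
#' per-gene DNA variant counts and the imprinting list into one design
#' row per gene: the response (`y_density`, `methylated`) and the six
#' transmit-type covariates.
#'
#' @param gmeth Output of [gene_methylation].
#' @param tcounts Output of [gene_transmit_counts].
#' @param gvar Optional output of [gene_variation] (for `n_var_dna`).
#' @param imprinted_ids Optional character vector of imprinted gene ids.
#' @return data.frame: `gene_id`, `y_density`, `methylated`, `x01_00` ...
#'   `x11_11`, `n_var_dna`, `imprinted`.
#' @export
feature_rows <- function(gmeth, tcounts, gvar = NULL,
                         imprinted_ids = character()) {
  rows <- data.frame(gene_id = gmeth$gene_id, y_density = gmeth$density,
                     methylated = gmeth$methylated)
  rows <- merge(rows, tcounts, by = "gene_id", sort = TRUE)
  if (!is.null(gvar))
    rows <- merge(rows,
                  data.frame(gene_id = gvar$gene_id, n_var_dna = gvar$n_var),
                  by = "gene_id", sort = TRUE)
  else rows$n_var_dna <- NA_integer_
  rows$imprinted <- rows$gene_id %in% imprinted_ids
  rows[order(rows$gene_id), , drop = FALSE]
}

# model matrix for the six transmit-type covariates with constant and
# collinear columns dropped; internal
.design <- function(rows) {
  cols <- intersect(.transmit_cols(), names(rows))
  X <- as.matrix(rows[, cols, drop = FALSE])
  dropped <- data.frame(term = character(), reason = character())
  const <- apply(X, 2, function(c) length(unique(c)) == 1)
  if (any(const)) {
    reason <- ifelse(colSums(X[, const, drop = FALSE] != 0) == 0,
                     "all zero", "constant")
    dropped <- rbind(dropped, data.frame(term = colnames(X)[const],
                                         reason = reason))
    X <- X[, !const, drop = FALSE]
  }
  if (ncol(X)) {
    q <- qr(cbind(1, X))
    if (q$rank < ncol(X) + 1) {
      keep_idx <- sort(q$pivot[seq_len(q$rank)])
      coll <- setdiff(seq_len(ncol(X) + 1), keep_idx) - 1L
      dropped <- rbind(dropped, data.frame(term = colnames(X)[coll],
                                           reason = "collinear"))
      X <- X[, -coll, drop = FALSE]
    }
  }
  list(X = X, dropped = dropped)
}

.term_table <- function(coefs) {
  term <- rownames(coefs)
  term[term != "(Intercept)"] <- transmit_label(term[term != "(Intercept)"])
  data.frame(term = term, estimate = coefs[, 1], std_error = coefs[, 2],
             statistic = coefs[, 3], p_value = coefs[, 4],
             row.names = NULL)
}

#' Logistic model: gene methylation on transmit-type counts
#'
#' Maximum-likelihood fit of the methylation indicator on the six
#' transmit-type counts with intercept:
#' `logit P(methylated) = b0 + sum_j b_j x_j`. All-zero, constant or
#' collinear covariates are dropped and listed; inference is Wald
#' (two-sided z). Complete separation is a declared failure naming the
#' separating covariate, never a silent huge coefficient. The fit is
#' deterministic in the rows and invariant to row order.
#'
#' @param rows Feature table (see [feature_rows]).
#' @return List of class `m6a_fit`: `model`, `terms` (term, estimate,
#'   std_error, statistic, p_value), `n_obs`, `dropped_terms`,
#'   `residual_summary` (residual deviance).
#' @export
fit_logistic <- function(rows) {
  y <- as.integer(rows$methylated)
  if (length(unique(y)) < 2) stop("single-class response; cannot fit")
  if (min(table(y)) < 2) stop("need >= 2 rows in each response class")

  # separation screen before fitting. A covariate whose presence/absence
  # reproduces the response exactly separates the data completely: that is
  # a declared failure. A covariate observed only in one response class
  # (typical for the rare transmit types) has no finite ML coefficient and
  # is dropped with a reason, reproducing the familiar four-term tables
  # when the rare homozygous-dispersal types have one-sided support.
  pre_dropped <- data.frame(term = character(), reason = character())
  for (cn in intersect(.transmit_cols(), names(rows))) {
    x <- rows[[cn]]
    if (all(x == 0)) next
    if (all((x > 0) == (y == 1)) || all((x > 0) == (y == 0)))
      stop("logistic fit failed (complete or quasi-complete separation); ",
           "separating covariate: ", transmit_label(cn))
    s1 <- sum(x > 0 & y == 1); s0 <- sum(x > 0 & y == 0)
    if (s1 == 0 || s0 == 0) {
      pre_dropped <- rbind(pre_dropped,
                           data.frame(term = cn,
                                      reason = "one-class support (no finite estimate)"))
      rows[[cn]] <- 0L
    }
  }

  d <- .design(rows)
  d$dropped <- d$dropped[!(d$dropped$term %in% pre_dropped$term), ,
                         drop = FALSE]
  d$dropped <- rbind(pre_dropped, d$dropped)
  dat <- data.frame(y = y, d$X)
  fml <- if (ncol(d$X)) stats::as.formula(
    paste("y ~", paste(colnames(d$X), collapse = " + "))) else y ~ 1
  fit <- suppressWarnings(stats::glm(fml, family = stats::binomial(),
                                     data = dat,
                                     control = list(epsilon = 1e-12,
                                                    maxit = 100)))
  co <- summary(fit)$coefficients
  huge <- rownames(co) != "(Intercept)" &
    (abs(co[, 1]) > 15 | co[, 2] > 100)
  if (!fit$converged || any(huge)) {
    offender <- if (any(huge)) rownames(co)[which.max(abs(co[, 1]))] else "fit"
    if (offender != "(Intercept)" && offender != "fit")
      offender <- transmit_label(offender)
    stop("logistic fit failed (complete or quasi-complete separation); ",
         "separating covariate: ", offender)
  }
  structure(list(model = "logistic", terms = .term_table(co),
                 n_obs = length(y), dropped_terms = d$dropped,
                 residual_summary = c(deviance = stats::deviance(fit))),
            class = "m6a_fit")
}

#' Linear model: 6mA density on transmit-type counts
#'
#' Ordinary least squares of per-gene 6mA density on the six transmit-type
#' counts with intercept, for methylated genes (the caller restricts the
#' rows; density is identically zero otherwise). Same covariate-dropping
#' rules as [fit_logistic]; t statistics, two-sided p-values. A constant
#' response yields a degenerate fit (intercept = the constant, slopes 0,
#' flagged) rather than an error.
#'
#' @param rows Feature table rows, typically `rows[rows$methylated, ]`.
#' @return List of class `m6a_fit` as in [fit_logistic], with
#'   `residual_summary` the residual variance and a `degenerate` flag.
#' @export
fit_linear <- function(rows) {
  y <- rows$y_density
  d <- .design(rows)
  if (nrow(rows) < ncol(d$X) + 2)
    stop("need at least ", ncol(d$X) + 2, " rows")
  if (stats::var(y) == 0) {
    terms <- data.frame(
      term = c("(Intercept)", transmit_label(colnames(d$X))),
      estimate = c(y[1], rep(0, ncol(d$X))),
      std_error = 0, statistic = NA_real_, p_value = NA_real_)
    return(structure(list(model = "linear", terms = terms,
                          n_obs = length(y), dropped_terms = d$dropped,
                          residual_summary = c(sigma2 = 0), degenerate = TRUE),
                     class = "m6a_fit"))
  }
  dat <- data.frame(y = y, d$X)
  fml <- if (ncol(d$X)) stats::as.formula(
    paste("y ~", paste(colnames(d$X), collapse = " + "))) else y ~ 1
  fit <- stats::lm(fml, data = dat)
  co <- summary(fit)$coefficients
  structure(list(model = "linear", terms = .term_table(co),
                 n_obs = length(y), dropped_terms = d$dropped,
                 residual_summary = c(sigma2 = summary(fit)$sigma^2),
                 degenerate = FALSE),
            class = "m6a_fit")
}

#' @export
print.m6a_fit <- function(x, ...) {
  cat(x$model, "fit,", x$n_obs, "genes\n")
  print(x$terms, digits = 4)
  if (nrow(x$dropped_terms))
    cat("dropped:", paste(transmit_label(x$dropped_terms$term), "(",
                          x$dropped_terms$reason, ")", collapse = "; "), "\n")
  invisible(x)
}

#' Imprinting-gene contrasts on DNA variant counts
#'
#' Splits genes into four cells (methylated/unmethylated x
#' imprinted/non-imprinted) and t-tests `n_var_dna` for the four
#' comparisons: imprinted vs non-imprinted within the methylated and
#' within the unmethylated genes, and methylated vs unmethylated within
#' the imprinted and within the non-imprinted genes. An empty (or
#' single-gene) cell makes that comparison not-computable rather than an
#' error.
#'
#' @param rows Feature table with `methylated`, `imprinted`, `n_var_dna`.
#' @param imprinted_ids Optional; overrides the `imprinted` column.
#' @param var_equal Passed to [group_ratio_comparison].
#' @return data.frame, one row per comparison: `comparison`, `group1`,
#'   `group2`, `n1`, `n2`, `mean1`, `mean2`, `statistic`, `df`, `p_value`,
#'   `computable`.
#' @export
imprinting_contrasts <- function(rows, imprinted_ids = NULL, var_equal = TRUE) {
  if (!is.null(imprinted_ids)) rows$imprinted <- rows$gene_id %in% imprinted_ids
  cell <- function(m, i) rows$n_var_dna[rows$methylated == m & rows$imprinted == i]
  cells <- list(MI = cell(TRUE, TRUE), MN = cell(TRUE, FALSE),
                UI = cell(FALSE, TRUE), UN = cell(FALSE, FALSE))
  labels <- c(MI = "methylated-imprinted", MN = "methylated-non-imprinted",
              UI = "unmethylated-imprinted", UN = "unmethylated-non-imprinted")
  pairs <- list(c("MI", "MN"), c("UI", "UN"), c("MI", "UI"), c("MN", "UN"))
  out <- do.call(rbind, lapply(pairs, function(p) {
    a <- cells[[p[1]]]; b <- cells[[p[2]]]
    base <- data.frame(comparison = paste(labels[p[1]], "vs", labels[p[2]]),
                       group1 = labels[p[1]], group2 = labels[p[2]],
                       n1 = length(a), n2 = length(b),
                       mean1 = if (length(a)) mean(a) else NA_real_,
                       mean2 = if (length(b)) mean(b) else NA_real_)
    if (length(a) < 2 || length(b) < 2)
      return(cbind(base, statistic = NA_real_, df = NA_real_,
                   p_value = NA_real_, computable = FALSE))
    cr <- group_ratio_comparison(a, b, names = labels[p], var_equal = var_equal)
    cbind(base, statistic = cr$statistic, df = cr$df, p_value = cr$p_value,
          computable = TRUE)
  }))
  rownames(out) <- NULL
  out
}
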