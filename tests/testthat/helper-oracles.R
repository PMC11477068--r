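# Independent brute-force oracles. These deliberately avoid the package's
# interval/statistics machinery: plain loops, per-base scans and textbook
# formulas, so tests compare two independent routes.

oracle_sites_per_gene <- function(genes, sites) {
  vapply(seq_len(nrow(genes)), function(i) {
    sum(sites$chrom == genes$chrom[i] &
          sites$pos >= genes$start[i] & sites$pos <= genes$end[i] &
          sites$strand == genes$strand[i])
  }, 0L)
}

# per-base scan of every gene: coding-strand adenine count
oracle_gene_nA <- function(genes, genome) {
  vapply(seq_len(nrow(genes)), function(i) {
    s <- strsplit(as.character(genome[[genes$chrom[i]]]), "")[[1]]
    body <- s[genes$start[i]:genes$end[i]]
    sum(body == if (genes$strand[i] == "+") "A" else "T")
  }, 0L)
}

# region label of a single position within a single gene, by feature scan
oracle_region_label <- function(gm, gene_id, pos) {
  f <- gm$features[gm$features$gene_id == gene_id, , drop = FALSE]
  in_iv <- function(d) any(d$start <= pos & pos <= d$end)
  if (in_iv(f[f$type != "exon", , drop = FALSE])) return("UTR")
  if (in_iv(f[f$type == "exon", , drop = FALSE])) return("exon")
  "intron"
}

oracle_transmit_counts <- function(recs, genes) {
  types <- transmit_types()
  out <- matrix(0L, nrow(genes), length(types),
                dimnames = list(genes$gene_id, types))
  for (k in seq_len(nrow(recs))) {
    hit <- which(genes$chrom == recs$chrom[k] &
                   genes$start <= recs$pos[k] & recs$pos[k] <= genes$end)
    for (i in hit) out[i, recs$transmit_type[k]] <- out[i, recs$transmit_type[k]] + 1L
  }
  out
}

oracle_intersect_keys <- function(a_keys, b_keys) {
  keep <- logical(length(a_keys))
  for (i in seq_along(a_keys)) keep[i] <- a_keys[i] %in% b_keys
  keep
}

# textbook Student t (equal variance)
oracle_student_t <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  df <- na + nb - 2
  list(t = t, df = df, p = 2 * pt(-abs(t), df))
}

oracle_pearson <- function(x, y) {
  sum((x - mean(x)) * (y - mean(y))) /
    sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
}

# logistic regression by hand-rolled IRLS on a design matrix with intercept
oracle_logistic <- function(X, y, tol = 1e-12, maxit = 200) {
  X1 <- cbind(1, X)
  beta <- rep(0, ncol(X1))
  for (it in seq_len(maxit)) {
    eta <- as.vector(X1 %*% beta)
    mu <- 1 / (1 + exp(-eta))
    w <- mu * (1 - mu)
    z <- eta + (y - mu) / w
    fit <- solve(t(X1) %*% (w * X1), t(X1) %*% (w * z))
    if (max(abs(fit - beta)) < tol) { beta <- as.vector(fit); break }
    beta <- as.vector(fit)
  }
  mu <- 1 / (1 + exp(-as.vector(X1 %*% beta)))
  se <- sqrt(diag(solve(t(X1) %*% (mu * (1 - mu) * X1))))
  list(beta = unname(beta), se = unname(se))
}

# OLS via normal equations
oracle_ols <- function(X, y) {
  X1 <- cbind(1, X)
  xtx_inv <- solve(t(X1) %*% X1)
  beta <- as.vector(xtx_inv %*% t(X1) %*% y)
  res <- y - X1 %*% beta
  s2 <- sum(res^2) / (nrow(X1) - ncol(X1))
  list(beta = beta, se = unname(sqrt(diag(xtx_inv) * s2)))
}
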