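# Independent brute-force oracles.  These deliberately use naive loops and
# textbook formulas, never the package's own code paths.

# sample SD via explicit sum of squares
oracle_sd <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  sqrt(sum((x - m)^2) / (n - 1))
}

# geNorm M value by definitional double loop over the panel
oracle_m_value <- function(q, gene, panel) {
  others <- setdiff(panel, gene)
  total <- 0
  for (k in others) {
    ratios <- log2(q[gene, ] / q[k, ])
    total <- total + oracle_sd(ratios)
  }
  total / length(others)
}

# per-sample geometric mean by explicit product
oracle_nf <- function(q, genes) {
  out <- numeric(ncol(q))
  for (s in seq_len(ncol(q))) {
    prod_q <- 1
    for (g in genes) prod_q <- prod_q * q[g, s]
    out[s] <- prod_q^(1 / length(genes))
  }
  out
}

# pairwise variation V_n/n+1 from first principles
oracle_v <- function(q, ranked, n, metric = "sd") {
  nf_a <- oracle_nf(q, ranked[1:n])
  nf_b <- oracle_nf(q, ranked[1:(n + 1)])
  v <- oracle_sd(log2(nf_a / nf_b))
  if (metric == "variance") v^2 else v
}

# OLS slope/intercept/R^2 from the normal equations
oracle_ols <- function(x, y) {
  n <- length(x)
  sx <- sum(x); sy <- sum(y); sxy <- sum(x * y); sxx <- sum(x^2)
  slope <- (n * sxy - sx * sy) / (n * sxx - sx^2)
  intercept <- (sy - slope * sx) / n
  yhat <- intercept + slope * x
  ss_res <- sum((y - yhat)^2)
  ss_tot <- sum((y - sy / n)^2)
  list(slope = slope, intercept = intercept,
       r_squared = if (ss_tot == 0) 1 else 1 - ss_res / ss_tot)
}

# classical pooled-variance two-sample t on the given vectors
oracle_pooled_t <- function(ctrl, trt) {
  n1 <- length(ctrl); n2 <- length(trt)
  d <- mean(trt) - mean(ctrl)
  sp2 <- ((n1 - 1) * oracle_sd(ctrl)^2 + (n2 - 1) * oracle_sd(trt)^2) /
    (n1 + n2 - 2)
  se <- sqrt(sp2 * (1 / n1 + 1 / n2))
  tstat <- d / se
  list(d = d, se = se, t = tstat,
       p = 2 * pt(-abs(tstat), df = n1 + n2 - 2))
}

# Benjamini-Hochberg step-up by the definitional min-over-j loop
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  sorted <- p[o]
  adj <- numeric(m)
  for (i in seq_len(m)) {
    best <- Inf
    for (j in i:m) best <- min(best, m * sorted[j] / j)
    adj[i] <- min(best, 1)
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

# ---- fixture builders -----------------------------------------------------

# quantity_matrix object straight from a positive matrix (types optional)
make_qm <- function(q, types = NULL, efficiencies = NULL) {
  genes <- rownames(q); samples <- colnames(q)
  if (is.null(genes)) genes <- paste0("g", seq_len(nrow(q)))
  if (is.null(samples)) samples <- paste0("s", seq_len(ncol(q)))
  dimnames(q) <- list(genes, samples)
  if (is.null(types)) types <- rep("X", length(samples))
  if (is.null(efficiencies)) efficiencies <- rep(1, length(genes))
  structure(list(q = q, genes = genes, samples = samples,
                 sample_types = stats::setNames(types, samples),
                 efficiencies = stats::setNames(efficiencies, genes)),
            class = "quantity_matrix")
}

random_qm <- function(n_genes, n_samples, seed) {
  set.seed(seed)
  q <- matrix(2^rnorm(n_genes * n_samples, 0, 1), n_genes, n_samples,
              dimnames = list(paste0("g", seq_len(n_genes)),
                              paste0("s", seq_len(n_samples))))
  make_qm(q)
}

# small hand-built ct_table: 2 genes with standards + unknowns in 2 types
tiny_ct_table <- function() {
  std <- expand.grid(gene = c("ref1", "tgt1"), serial = 1:5,
                     stringsAsFactors = FALSE)
  std$sample <- "Std01"
  std$type <- "standard"
  std$ct <- 20 + (std$serial - 1) * log2(10)   # E = 1 exactly
  unk <- expand.grid(gene = c("ref1", "tgt1"),
                     sample = c("C_1", "C_2", "T_1", "T_2"),
                     stringsAsFactors = FALSE)
  unk$type <- ifelse(startsWith(unk$sample, "C"), "ctrl", "trt")
  unk$serial <- 1L
  unk$ct <- 22
  as_ct_table(rbind(std[names(unk)], unk))
}

# Ct table built directly from a quantity matrix at E = 1 (Ct = 30 - log2 q)
ct_table_from_quantities <- function(q, types) {
  genes <- rownames(q); samples <- colnames(q)
  unk <- expand.grid(gene = genes, sample = samples,
                     stringsAsFactors = FALSE)
  unk$type <- types[match(unk$sample, samples)]
  unk$serial <- 1L
  unk$ct <- 30 - log2(q[cbind(unk$gene, unk$sample)])
  as_ct_table(unk)
}
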