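test_that("delta-delta-Ct values calibrate the control geometric mean to 1", {
  # target and reference share identical Ct profiles -> value = 1 everywhere
  q <- matrix(2^rnorm(12), 2, 6,
              dimnames = list(NULL, paste0("s", 1:6)))
  q[2, ] <- q[1, ]
  rownames(q) <- c("ref", "tgt")
  types <- rep(c("ctrl", "trt"), each = 3)
  tab <- ct_table_from_quantities(q, types)
  nm <- normalize_targets(tab, control = "ctrl", ref_genes = "ref",
                          targets = "tgt")
  expect_equal(nm$value, rep(1, 6))
  # E = 1, target Ct one cycle lower in treated, references unchanged
  df <- expand.grid(gene = c("ref", "tgt"), sample = paste0("s", 1:6),
                    stringsAsFactors = FALSE)
  df$type <- rep(types, each = 2); df$serial <- 1L
  df$ct <- 24
  df$ct[df$gene == "tgt" & df$type == "trt"] <- 23
  nm2 <- normalize_targets(as_ct_table(df), control = "ctrl",
                           ref_genes = "ref", targets = "tgt")
  expect_equal(nm2$value[nm2$type == "trt"], rep(2, 3))
  expect_equal(nm2$value[nm2$type == "ctrl"], rep(1, 3))
  # control-type geometric mean is 1 per gene on random data
  set.seed(14)
  qr <- matrix(2^rnorm(30), 5, 6,
               dimnames = list(c("r1", "r2", "t1", "t2", "t3"),
                               paste0("s", 1:6)))
  nm3 <- normalize_targets(ct_table_from_quantities(qr, types),
                           control = "ctrl", ref_genes = c("r1", "r2"))
  for (g in c("t1", "t2", "t3")) {
    lv <- nm3$log2_value[nm3$gene == g & nm3$type == "ctrl"]
    expect_equal(mean(lv), 0, tolerance = 1e-12)
  }
  expect_equal(nm3$log2_value, log2(nm3$value), tolerance = 1e-12)
  # a gene cannot be both reference and target
  expect_error(normalize_targets(tab, control = "ctrl", ref_genes = "ref",
                                 targets = c("ref", "tgt")), "both")
})

test_that("ratios, t statistics and p values match closed-form oracles", {
  mk_norm <- function(ctrl_log2, trt_log2) {
    df <- data.frame(
      gene = "g", sample = paste0("s", seq_along(c(ctrl_log2, trt_log2))),
      type = rep(c("ctrl", "trt"), c(length(ctrl_log2), length(trt_log2))),
      value = 2^c(ctrl_log2, trt_log2),
      log2_value = c(ctrl_log2, trt_log2))
    attr(df, "control") <- "ctrl"
    class(df) <- c("normalized_expression", "data.frame")
    df
  }
  # identical groups -> R = 1, t = 0, p = 1
  r <- expression_ratios(mk_norm(c(0, 0, 0), c(0, 0, 0)))
  expect_equal(r$ratio, 1)
  expect_equal(r$p, 1)
  # fixed 3-vs-3 example vs the pooled-t closed form
  ctrl <- c(0.12, -0.31, 0.05); trt <- c(1.4, 0.9, 1.15)
  r2 <- expression_ratios(mk_norm(ctrl, trt))
  ora <- oracle_pooled_t(ctrl, trt)
  expect_equal(r2$t, ora$t, tolerance = 1e-10)
  expect_equal(r2$p, ora$p, tolerance = 1e-10)
  expect_equal(r2$ratio, 2^ora$d, tolerance = 1e-10)
  expect_equal(r2$se_ratio, 2^ora$d * log(2) * ora$se, tolerance = 1e-10)
  expect_equal(r2$se_log2, ora$se, tolerance = 1e-10)
  # stats::t.test as an independent second oracle, both flavors
  tt <- t.test(trt, ctrl, var.equal = TRUE)
  expect_equal(r2$p, tt$p.value, tolerance = 1e-12)
  r2w <- expression_ratios(mk_norm(ctrl, trt), var_equal = FALSE)
  ttw <- t.test(trt, ctrl)
  expect_equal(r2w$p, ttw$p.value, tolerance = 1e-12)
  # near-degenerate strong effect: R -> 2, p small
  r3 <- expression_ratios(mk_norm(c(-1e-6, 0, 1e-6), c(1 - 1e-6, 1, 1 + 1e-6)))
  expect_equal(r3$ratio, 2, tolerance = 1e-5)
  expect_lt(r3$p, 1e-10)
  # a side with fewer than 2 samples is an error naming gene and type
  expect_error(expression_ratios(mk_norm(c(0, 0), 1)), "g.*trt")
})

test_that("BH adjustment implements the step-up definition", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03)), c(0.03, 0.03, 0.03))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.04, 6)), rep(0.04, 6))
  expect_error(bh_adjust(c(0.1, 1.2)), "0, 1")
  set.seed(9)
  for (i in 1:30) {
    p <- runif(sample(1:40, 1))
    adj <- bh_adjust(p)
    expect_equal(adj, oracle_bh(p), tolerance = 1e-12)
    expect_equal(adj, p.adjust(p, method = "BH"), tolerance = 1e-12)
    expect_true(all(adj >= p - 1e-15))
  }
})

test_that("per-sample loading errors cancel exactly in ratios", {
  sim <- generate_dataset(
    simulation_design(n_samples_per_type = 4L, true_efficiencies = 0.95),
    seed = 17)
  tab <- sim$table
  eff <- sim$truth$efficiencies
  refs <- sim$truth$designed_order[1:3]
  run <- function(t) {
    nm <- normalize_targets(t, control = "C05", ref_genes = refs,
                            efficiencies = eff,
                            targets = sim$truth$design$target_genes)
    expression_ratios(nm)
  }
  before <- run(tab)
  # simulate a loading error: multiply every gene's quantity in one sample
  # by 3, i.e. subtract log_{1+E}(3) cycles from that sample's Ct
  bump <- tab
  hit <- bump$sample == "T05_02" & bump$role == "unknown"
  bump$ct[hit] <- bump$ct[hit] - log(3) / log(1 + eff[bump$gene[hit]])
  after <- run(bump)
  expect_equal(after$ratio, before$ratio, tolerance = 1e-10)
  expect_equal(after$p, before$p, tolerance = 1e-10)
})

test_that("the exported per-sample dataset reproduces ratios on re-import", {
  sim <- generate_dataset(simulation_design(n_samples_per_type = 3L),
                          seed = 23)
  nm <- normalize_targets(sim$table, control = "C05",
                          ref_genes = sim$truth$designed_order[1:4],
                          targets = sim$truth$design$target_genes)
  expect_equal(nrow(nm), length(sim$truth$design$target_genes) * 9L)
  dir <- withr::local_tempdir()
  export_exp_dataset(nm, dir)
  back <- read_exp_dataset(dir, control = "C05")
  expect_equal(expression_ratios(back), expression_ratios(nm),
               tolerance = 1e-10)
})
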