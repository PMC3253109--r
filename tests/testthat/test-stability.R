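test_that("quantities follow the efficiency-corrected closed form", {
  df <- expand.grid(gene = c("a", "b"), sample = c("s1", "s2"),
                    stringsAsFactors = FALSE)
  df$type <- "ctrl"; df$serial <- 1L
  df$ct <- c(20, 24, 21, 26)  # a: 20,21 ; b: 24,26
  tab <- as_ct_table(df)
  # E = 1: one cycle difference = one doubling
  qm <- build_quantity_matrix(tab)
  expect_equal(unname(qm$q["a", ]), c(1, 0.5))
  # E = 0.9, Ct_cal - Ct = 2 -> q = 1.9^2
  qm2 <- build_quantity_matrix(tab, efficiencies = c(a = 1, b = 0.9))
  expect_equal(unname(qm2$q["b", "s2"]), 1.9^-2)
  expect_equal(unname(qm2$q["b", "s1"]), 1)
  # min-Ct calibrator: every gene's maximum quantity is exactly 1
  set.seed(5)
  big <- expand.grid(gene = paste0("g", 1:4), sample = paste0("s", 1:6),
                     stringsAsFactors = FALSE)
  big$type <- "ctrl"; big$serial <- 1L; big$ct <- runif(24, 18, 30)
  qb <- build_quantity_matrix(as_ct_table(big))
  expect_equal(unname(apply(qb$q, 1, max)), rep(1, 4))
  # control-mean calibrator: control-type geometric mean is exactly 1
  big$type <- rep(c("ctrl", "ctrl", "ctrl", "trt", "trt", "trt"), each = 4)
  qc <- build_quantity_matrix(as_ct_table(big), calibrator = "control_mean",
                              control = "ctrl")
  ctrl_cols <- names(qc$sample_types)[qc$sample_types == "ctrl"]
  expect_equal(unname(exp(rowMeans(log(qc$q[, ctrl_cols])))), rep(1, 4))
  # a requested gene missing from the table is an error naming it
  expect_error(build_quantity_matrix(tab, genes = c("a", "nope")), "nope")
})

test_that("pairwise log-ratio SD is symmetric and matches hand values", {
  # proportional profiles -> SD exactly 0
  q <- rbind(a = c(1, 2, 4), b = 3 * c(1, 2, 4))
  expect_equal(pairwise_sd(make_qm(q), "a", "b"), 0)
  # log2-ratios {0, 1} -> SD = sqrt(1/2)
  q2 <- rbind(a = c(1, 2), b = c(1, 1))
  expect_equal(pairwise_sd(make_qm(q2), "a", "b"), sqrt(0.5))
  for (seed in 1:10) {
    qm <- random_qm(3, 5, seed)
    expect_equal(pairwise_sd(qm, "g1", "g2"), pairwise_sd(qm, "g2", "g1"))
  }
})

test_that("M values match the brute-force definition", {
  # fully proportional panel -> all M = 0
  base <- c(1, 3, 0.5, 2)
  q <- rbind(a = base, b = 2 * base, c = 0.1 * base)
  qm <- make_qm(q)
  for (g in c("a", "b", "c")) expect_equal(m_value(qm, g), 0)
  # random matrices vs definitional double loop
  for (seed in 1:25) {
    qm <- random_qm(4, 4, seed)
    for (g in qm$genes) {
      expect_equal(m_value(qm, g), oracle_m_value(qm$q, g, qm$genes),
                   tolerance = 1e-10)
    }
  }
  # duplicated sample column keeps every M finite
  qm <- random_qm(4, 4, 99)
  q2 <- cbind(qm$q, s5 = qm$q[, 4])
  qm2 <- make_qm(q2)
  for (g in qm2$genes) expect_true(is.finite(m_value(qm2, g)))
  expect_error(m_value(qm, "g1", panel = "g1"), ">= 2")
})

test_that("stepwise exclusion ranks genes and flags the designed outlier", {
  set.seed(21)
  base <- 2^rnorm(8, 0, 1)
  q <- rbind(a = base, b = 1.5 * base, c = 0.7 * base,
             noisy = base * 2^rnorm(8, 0, 1))
  rk <- rank_stability(make_qm(q))
  expect_equal(sort(rk$rank), 1:4)
  expect_equal(rk$gene[rk$rank == 4], "noisy")
  expect_equal(rk$exclusion_round[rk$gene == "noisy"], 1L)
  expect_equal(sum(rk$exclusion_round == 0L), 3L)
  expect_error(rank_stability(make_qm(q[1:2, ])), ">= 3")
})

test_that("M values are invariant to gene scaling and reordering", {
  qm <- random_qm(5, 6, 7)
  rk <- rank_stability(qm)
  # multiplying one gene's quantities by a constant changes nothing
  q2 <- qm$q; q2["g3", ] <- 1000 * q2["g3", ]
  rk2 <- rank_stability(make_qm(q2))
  expect_equal(rk2, rk)
  # permuting samples and genes preserves M values and ranks
  perm_q <- qm$q[c(4, 2, 5, 1, 3), c(3, 1, 6, 2, 5, 4)]
  rk3 <- rank_stability(make_qm(perm_q))
  expect_equal(rk3[order(rk3$gene), c("gene", "m_value", "rank")],
               rk[order(rk$gene), c("gene", "m_value", "rank")],
               ignore_attr = TRUE)
})

test_that("iterative panels agree with the brute-force oracle throughout", {
  for (seed in 1:10) {
    qm <- random_qm(5, 6, seed + 100)
    panel <- qm$genes
    while (length(panel) >= 3) {
      m_pkg <- qpcrkit:::panel_m_values(qm, panel)
      for (g in panel) {
        expect_equal(unname(m_pkg[g]), oracle_m_value(qm$q, g, panel),
                     tolerance = 1e-10)
      }
      panel <- setdiff(panel, names(which.max(m_pkg)))
    }
  }
})

test_that("maximal-M ties exclude the lexicographically later gene", {
  base <- c(1, 2, 4, 8)
  jig <- 2^c(0, 1, 0, 1)
  q <- rbind(aa = base, bb = base * jig, cc = base * jig,
             dd = base, ee = base)
  # bb and cc are identical noisy twins sharing the maximal M; the
  # lexicographically later twin (cc) must leave first
  rk <- rank_stability(make_qm(q))
  expect_equal(rk$gene[rk$rank == 5], "cc")
  expect_equal(rk$gene[rk$rank == 4], "bb")
  # final trio is all-zero M; ties rank lexicographically earlier better
  expect_equal(rk$gene[rk$rank == 1], "aa")
  expect_equal(rk$gene[rk$exclusion_round == 0L], c("aa", "dd", "ee"))
})
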