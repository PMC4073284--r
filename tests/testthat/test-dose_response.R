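test_that("size factors recover exact library-scale ratios", {
  set.seed(2)
  base <- matrix(rpois(600, 100), ncol = 3,
                 dimnames = list(sprintf("g%d", 1:200), c("a", "b", "c")))
  doubled <- base
  doubled[, 2] <- base[, 1] * 2L   # sample b is exactly twice sample a
  res <- size_factor_normalize(doubled)
  expect_equal(res$size_factors[["b"]] / res$size_factors[["a"]], 2,
               tolerance = 1e-9)
  expect_equal(res$normalized[, "a"], res$normalized[, "b"] / 1,
               tolerance = 1e-9, ignore_attr = TRUE)
  # identical samples: all factors exactly 1
  same <- cbind(base[, 1], base[, 1], base[, 1])
  colnames(same) <- c("a", "b", "c")
  expect_equal(unname(size_factor_normalize(same)$size_factors), c(1, 1, 1))
  # random NB matrix equals the direct median-of-ratios oracle
  nb <- matrix(rnbinom(1000, mu = 80, size = 10), ncol = 5,
               dimnames = list(sprintf("g%d", 1:200), sprintf("s%d", 1:5)))
  expect_equal(unname(size_factor_normalize(nb)$size_factors),
               unname(oracle_size_factors(nb)), tolerance = 1e-12)
})

test_that("normalization is idempotent", {
  set.seed(3)
  m <- matrix(rnbinom(800, mu = 60, size = 5), ncol = 4,
              dimnames = list(sprintf("g%d", 1:200), sprintf("s%d", 1:4)))
  m[, 3] <- m[, 3] * 3L
  norm1 <- size_factor_normalize(m)
  norm2 <- size_factor_normalize(norm1$normalized)
  expect_equal(unname(norm2$size_factors), rep(1, 4), tolerance = 1e-9)
  expect_error(size_factor_normalize(matrix(c(0, 1, 1, 0), 2,
                                            dimnames = list(c("g1", "g2"),
                                                            c("a", "b")))),
               "pseudo-reference")
})

dose_design <- function(doses = c(0, 1, 2.5, 5, 10), clone = "WT") {
  data.frame(sample = sprintf("%s_s%d", clone, seq_along(doses)),
             clone = clone, dose = doses)
}

test_that("dose correlation handles perfect, constant and affine cases", {
  des <- dose_design()
  expr <- rbind(lin = 2 * des$dose + 5, const = rep(7, 5))
  colnames(expr) <- des$sample
  res <- dose_correlation(expr, des)
  expect_equal(res$r[res$gene_id == "lin"], 1, tolerance = 1e-12)
  expect_lt(res$p[res$gene_id == "lin"], 0.01)
  expect_true(is.na(res$r[res$gene_id == "const"]))
  expect_equal(res$p[res$gene_id == "const"], 1)
  # affine invariance of r; sign flip under dose negation
  expr2 <- rbind(lin = 100 - 3 * (2 * des$dose + 5))
  colnames(expr2) <- des$sample
  res2 <- dose_correlation(expr2, des)
  expect_equal(abs(res2$r), 1, tolerance = 1e-12)
  expect_equal(res2$r, -1, tolerance = 1e-12)
  expect_error(dose_correlation(expr, des[1:2, ]), "< 3")
})

test_that("null gene p-values are approximately uniform", {
  set.seed(8)
  des <- dose_design(rep(c(0, 1, 2.5, 5, 10, 25), each = 3))
  expr <- matrix(rnbinom(2000 * nrow(des), mu = 100, size = 10),
                 nrow = 2000, dimnames = list(sprintf("g%d", 1:2000),
                                              des$sample))
  res <- dose_correlation(expr, des)
  ks <- ks.test(res$p, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("the three-criterion screen classifies example genes correctly", {
  cor_results <- data.frame(
    gene_id = rep(c("hit", "wt6only"), 3),
    clone = rep(c("WT6", "WT10", "MUT3"), each = 2),
    r = c(0.95, 0.9, 0.92, 0.1, 0.2, 0.05),
    p = c(0.004, 0.004, 0.007, 0.4, 0.4, 0.9))
  lfc_results <- data.frame(gene_id = rep(c("hit", "wt6only"), 2),
                            clone = rep(c("WT6", "WT10"), each = 2),
                            lfc_lowest = c(0.8, 0.8, 0.9, 0.0))
  out <- screen_targets(cor_results, lfc_results, c("WT6", "WT10"), "MUT3")
  expect_equal(out$classification[out$gene_id == "hit"], "UP")
  expect_equal(out$classification[out$gene_id == "wt6only"], "none")
  # UP and DOWN are disjoint by construction
  expect_true(all(table(out$gene_id,
                        out$classification %in% c("UP", "DOWN")) <= 1))
  expect_error(screen_targets(cor_results[cor_results$clone != "MUT3", ],
                              lfc_results, c("WT6", "WT10"), "MUT3"),
               "missing clone")
})

test_that("a null dose matrix yields an (almost) empty screen", {
  d <- simulate_dose_counts(seed = 17, n_genes = 400, n_up = 0, n_down = 0)
  nm <- size_factor_normalize(d$counts)
  sc <- screen_targets(dose_correlation(nm$normalized, d$design,
                                        dose_transform = log1p),
                       lowest_dose_log2fc(nm$normalized, d$design),
                       c("WT6", "WT10"), "MUT3")
  expect_lte(mean(sc$classification != "none"), 0.01)
})

test_that("binding integration reports bound fractions and a Fisher test", {
  screen <- data.frame(gene_id = sprintf("g%d", 1:40),
                       classification = rep(c("UP", "DOWN"), each = 20))
  tt <- data.frame(gene_id = sprintf("g%d", 1:40),
                   tag_total = rep(150L, 40))
  res <- integrate_binding(screen, tt)
  expect_equal(res$summary$fraction_bound, c(1, 1))
  expect_equal(res$fisher_p, 1)
  # asymmetric binding matches the enumeration oracle
  tt2 <- tt; tt2$tag_total <- c(rep(150L, 15), rep(10L, 25))
  res2 <- integrate_binding(screen, tt2)
  tbl <- rbind(c(15, 5), c(0, 20))
  expect_equal(res2$fisher_p, oracle_fisher_p(tbl), tolerance = 1e-9)
})

test_that("signature scores are column sums over the gene set", {
  z <- matrix(0, 16, 4, dimnames = list(sprintf("w%d", 1:16),
                                        sprintf("s%d", 1:4)))
  genes <- rownames(z)
  expect_equal(unname(signature_score(z, genes)), rep(0, 4))
  z1 <- z + 1
  expect_equal(unname(signature_score(z1, genes)), rep(16, 4))
  set.seed(5)
  zr <- matrix(rnorm(64), 16, 4, dimnames = dimnames(z))
  expect_equal(signature_score(zr, genes[1:7]),
               colSums(zr[genes[1:7], ]))
  expect_warning(signature_score(zr, c(genes[1:3], "absent")), "missing")
  expect_error(signature_score(zr, "absent"), "no gene")
})
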