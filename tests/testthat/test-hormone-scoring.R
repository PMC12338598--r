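test_that("wilcoxon rank-sum reproduces exact enumeration values", {
  # complete separation: the two most extreme of C(6,3)=20 assignments
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(10, 11, 12)), 2 / 20,
               tolerance = 1e-12)
  # C(8,4) = 70 assignments
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3, 4), c(10, 11, 12, 13)), 2 / 70,
               tolerance = 1e-12)
  expect_equal(wilcoxon_rank_sum(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_equal(wilcoxon_rank_sum(rep(2, 4), rep(2, 5)), 1)  # degenerate ties
  expect_error(wilcoxon_rank_sum(numeric(0), 1), "non-empty")
})

test_that("wilcoxon p equals full enumeration for all tie-free small samples", {
  set.seed(77)
  for (i in 1:40) {
    nx <- sample(2:5, 1)
    ny <- sample(2:5, 1)
    v <- sample(1:100, nx + ny)           # distinct -> tie-free
    x <- v[1:nx]; y <- v[-(1:nx)]
    expect_equal(wilcoxon_rank_sum(x, y), wilcoxon_enum_oracle(x, y),
                 tolerance = 1e-12,
                 info = sprintf("nx=%d ny=%d", nx, ny))
  }
})

test_that("wilcoxon p is symmetric and valid with ties under the approximation", {
  set.seed(78)
  x <- sample(1:10, 30, replace = TRUE)
  y <- sample(2:11, 35, replace = TRUE)
  p <- wilcoxon_rank_sum(x, y)
  expect_equal(p, wilcoxon_rank_sum(y, x), tolerance = 1e-12)
  expect_true(p > 0 && p <= 1)
})

test_that("star annotation divides the base levels by the group count", {
  # 17 clusters: the printed per-cluster thresholds
  expect_equal(0.05 / 17, 0.00294, tolerance = 1e-3)
  expect_equal(star_annotation(0.5, 17), 0L)
  expect_equal(star_annotation(0.0029, 17), 1L)
  expect_equal(star_annotation(0.0005, 17), 2L)
  expect_equal(star_annotation(5e-5, 17), 3L)
  expect_equal(star_annotation(1e-7, 17), 4L)
  expect_equal(star_annotation(c(1, 1e-7), 1), c(0L, 4L))
})

test_that("identical score distributions give diff 0 and no significance", {
  set.seed(101)
  scores <- matrix(rep(runif(40, 1, 3), 2), ncol = 2,
                   dimnames = list(paste0("c", 1:40), c("auxin_up", "auxin_down")))
  cl <- rep(c("k0", "k1"), each = 20)
  geno <- rep(c("WT", "mutant", "WT", "mutant"), each = 10)
  # mutant scores mirror WT exactly within each cluster
  scores[geno == "mutant", ] <- scores[geno == "WT", ]
  ct <- contrast_clusters(scores, cl, geno)
  expect_equal(ct$diff, rep(0, nrow(ct)))
  expect_false(any(ct$significant))
  expect_equal(ct$p, rep(1, nrow(ct)))
  expect_equal(ct$dot_size, rep(0, nrow(ct)))   # log10(1/1) = 0
})

test_that("the Bonferroni family is counted from the inputs", {
  set.seed(102)
  n_cl <- 4; n_sets <- 3
  scores <- matrix(runif(n_cl * 20 * n_sets), ncol = n_sets,
                   dimnames = list(NULL, c("a_up", "a_down", "b_up")))
  rownames(scores) <- paste0("c", seq_len(nrow(scores)))
  cl <- rep(paste0("k", 1:n_cl), each = 20)
  geno <- rep_len(c("WT", "mutant"), nrow(scores))
  ct <- contrast_clusters(scores, cl, geno, alpha = 0.05)
  expect_equal(attr(ct, "bonferroni_threshold"), 0.05 / (n_cl * n_sets))
  expect_equal(attr(ct, "star_family"), n_cl)
  expect_equal(nrow(ct), n_cl * n_sets)
  # 17 clusters x 12 sets at alpha 0.05 reproduces the printed threshold
  expect_equal(round(0.05 / (17 * 12), 6), 0.000245)
})

test_that("significance calls are invariant to cluster relabeling", {
  cfg <- sc_sim_config(n_genes = 500, n_cells_per_cluster = 50,
                       genes_per_set = 10, seed = 12,
                       beta = c(auxin = 0.3, cytokinin = 0, brassinosteroid = 0,
                                abscisic_acid = 0, gibberellin = 0, ethylene = 0),
                       latent_mean = matrix(c(0, 1, 0, 0, 0, 0), 2, 3,
                                            dimnames = list(c("WT", "mutant"),
                                                            c("c0", "c1", "c2"))))
  sim <- simulate_sc(cfg)
  sc <- score_cells(sim$sce, sim_gene_sets(cfg))
  ct1 <- contrast_clusters(sc, sim$truth$cluster, sim$truth$genotype)
  relab <- c(c0 = "zebra", c1 = "alpha", c2 = "mid")
  ct2 <- contrast_clusters(sc, relab[sim$truth$cluster], sim$truth$genotype)
  key1 <- paste(relab[ct1$cluster], ct1$hormone, ct1$direction)
  key2 <- paste(ct2$cluster, ct2$hormone, ct2$direction)
  expect_equal(ct1$significant[order(key1)], ct2$significant[order(key2)])
  expect_equal(ct1$p[order(key1)], ct2$p[order(key2)], tolerance = 1e-12)
})

test_that("a planted latent shift yields the correct signed significant calls", {
  lm <- matrix(0, 2, 3, dimnames = list(c("WT", "mutant"), c("c0", "c1", "c2")))
  lm["mutant", "c1"] <- 1
  cfg <- sc_sim_config(n_cells_per_cluster = 150, seed = 55,
                       beta = c(auxin = 0, cytokinin = 0, brassinosteroid = 0.2,
                                abscisic_acid = 0, gibberellin = 0, ethylene = 0),
                       latent_mean = lm)
  sim <- simulate_sc(cfg)
  sc <- score_cells(sim$sce, sim_gene_sets(cfg))
  ct <- contrast_clusters(sc, sim$truth$cluster, sim$truth$genotype)
  up <- ct[ct$cluster == "c1" & ct$hormone == "brassinosteroid" &
             ct$direction == "up", ]
  down <- ct[ct$cluster == "c1" & ct$hormone == "brassinosteroid" &
               ct$direction == "down", ]
  expect_true(up$significant); expect_gt(up$diff, 0)
  expect_true(down$significant); expect_lt(down$diff, 0)
  # dot size decreases in p
  expect_true(all(diff(ct$dot_size[order(ct$p)]) <= 1e-12))
  # directional inference reads the pair as higher signaling in the mutant
  call <- infer_direction(up, down)
  expect_equal(call$call, "higher_in_mutant")
  expect_equal(call$confidence, "strong")
})

test_that("direction inference covers weak and inconclusive evidence", {
  row <- function(dir, diff, sig)
    data.frame(cluster = "c1", hormone = "br", direction = dir,
               diff = diff, significant = sig)
  expect_equal(infer_direction(row("up", 0.1, FALSE), row("down", -0.2, TRUE)),
               list(call = "higher_in_mutant", confidence = "weak"))
  expect_equal(infer_direction(row("up", -0.3, TRUE), row("down", 0.2, TRUE)),
               list(call = "lower_in_mutant", confidence = "strong"))
  expect_equal(infer_direction(row("up", 0.1, FALSE), row("down", 0.1, FALSE))$call,
               "inconclusive")
  # conflicting evidence is inconclusive, not a coin flip
  expect_equal(infer_direction(row("up", 0.3, TRUE), row("down", 0.3, TRUE))$call,
               "inconclusive")
  expect_error(infer_direction(row("up", 1, TRUE),
                               transform(row("down", 1, TRUE), cluster = "c2")),
               "same")
})

test_that("clusters with too few cells in a genotype yield p = 1 with a warning", {
  scores <- matrix(runif(10), ncol = 1, dimnames = list(NULL, "a_up"))
  rownames(scores) <- paste0("c", 1:10)
  cl <- rep("k0", 10)
  geno <- c(rep("WT", 9), "mutant")
  expect_warning(ct <- contrast_clusters(scores, cl, geno), "< 2 cells")
  expect_equal(ct$p, 1)
  expect_false(ct$significant)
})
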