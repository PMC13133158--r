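test_that("decimal rounding reproduces the printed screen classifications", {
  # binary float rounding would send 1.95 to 1.9; the decimal rule must not
  expect_equal(round_half_up(1.95, 1), 2.0)
  expect_equal(round_half_up(2.23825, 1), 2.2)
  expect_equal(round_half_up(2.0625, 1), 2.1)
  expect_equal(round_half_up(-1.9875, 1), -2.0)
  expect_equal(round_half_up(-1.775, 1), -1.8)
  expect_equal(round_half_up(-1.7475, 1), -1.7)
  expect_equal(round_half_up(1.9499, 1), 1.9)
  expect_equal(round_half_up(0, 1), 0)
  expect_equal(round_half_up(c(0.05, 0.25, 2.35), 1), c(0.1, 0.3, 2.4))
  expect_equal(round_half_up(1.95, 0), 2)
  expect_equal(round_half_up(2.23825, 3), 2.238)
})

test_that("decimal rounding is symmetric about zero on a dense grid", {
  x <- seq(-3, 3, by = 0.005)
  expect_equal(round_half_up(x, 1), -round_half_up(-x, 1))
  x2 <- round(runif(200, -5, 5), 4)
  expect_equal(round_half_up(x2, 1), -round_half_up(-x2, 1))
})

test_that("RPM normalisation scales every column to one million", {
  m <- cbind(a = c(10, 20, 30, 40), b = c(1, 1, 0, 0))
  rpm <- normalize_rpm(m)
  expect_equal(rpm[, "a"], c(1e5, 2e5, 3e5, 4e5))
  expect_equal(rpm[, "b"], c(5e5, 5e5, 0, 0))
  expect_equal(unname(colSums(rpm)), c(1e6, 1e6))
  expect_equal(unname(normalize_rpm(matrix(7, 1, 1))[1, 1]), 1e6)
  expect_error(normalize_rpm(cbind(ok = 1:2, zero = c(0, 0))), "zero")
  expect_error(normalize_rpm(cbind(x = c(-1, 2))), "non-negative")
})

test_that("sgRNA fold changes follow the pseudocount arithmetic", {
  expect_equal(unname(sgrna_lfc(c(100, 200), c(100, 200))), c(0, 0))
  # 4x control with RPM >> pseudocount
  expect_equal(unname(sgrna_lfc(4e5, 1e5)), 2, tolerance = 1e-4)
  # zero treatment against control RPM 999: log2(1) - log2(1000)
  expect_equal(unname(sgrna_lfc(0, 999)), log2(1) - log2(1000))
  # replicates averaged on the RPM scale before log2
  expect_equal(unname(sgrna_lfc(matrix(c(100, 300), 1), matrix(c(50, 150), 1))),
               log2(201) - log2(101))
})

test_that("gene aggregation applies the rounded-LFC hit rule", {
  lfc <- c(t1 = 1.9, t2 = 2.0, p1 = -2.05, p2 = -1.925, n1 = 0.3,
           c1 = 5)
  map <- data.frame(sgrna = names(lfc),
                    gene = c("TYK2like", "TYK2like", "PLCG1like",
                             "PLCG1like", "neutral", "control"))
  res <- gene_lfc_and_hits(lfc, map)
  expect_false("control" %in% res$gene)
  ty <- res[res$gene == "TYK2like", ]
  expect_equal(ty$lfc, 1.95)
  expect_equal(ty$lfc_rounded, 2.0)
  expect_equal(ty$hit, "enriched")   # borderline rescue case: decimal rounding decides
  pl <- res[res$gene == "PLCG1like", ]
  expect_equal(pl$lfc, -1.9875)
  expect_equal(pl$lfc_rounded, -2.0)
  expect_equal(pl$hit, "depleted")
  expect_equal(res[res$gene == "neutral", "hit"], "none")
})

test_that("hit calls are invariant to sgRNA and replicate ordering", {
  sc <- generate_screen(screen_config(seed = 8, n_genes = 60,
                                      n_controls = 40))
  res1 <- score_screen(sc, paste0("treatment_", 1:3), paste0("control_", 1:3))
  perm <- sample(nrow(sc$counts))
  sc2 <- list(counts = sc$counts[perm, c(1, 4, 2, 3, 7, 5, 6)],
              guide_map = sc$guide_map[rev(seq_len(nrow(sc$guide_map))), ])
  res2 <- score_screen(sc2, paste0("treatment_", c(3, 1, 2)),
                       paste0("control_", c(2, 3, 1)))
  res2 <- res2[match(res1$gene, res2$gene), ]
  expect_equal(res1$lfc, res2$lfc)
  expect_equal(res1$hit, res2$hit)
})

test_that("control sgRNA fold changes are centred near zero under the null", {
  sc <- generate_screen(screen_config(seed = 9, rescue_effect = 1,
                                      depletion_effect = 1))
  res <- score_screen(sc, paste0("treatment_", 1:3), paste0("control_", 1:3))
  ctrl <- attr(res, "sgrna_lfc")[sc$guide_map$gene == "control"]
  expect_lt(abs(mean(ctrl)), 0.05)
})

test_that("hypergeometric gene p matches the closed form and enumeration", {
  # 4 guides occupying ranks 1-4 of 1000
  map <- data.frame(sgrna = paste0("s", 1:1000),
                    gene = c(rep("hit", 4), rep("other", 996)))
  p <- hypergeom_gene_p(paste0("s", 1:1000), map, "hit",
                        inclusion_fraction = 0.1)
  expect_equal(p, 1 / choose(1000, 4), tolerance = 1e-10)

  # exhaustive enumeration oracle on small lists
  set.seed(61)
  for (rep in 1:5) {
    N <- sample(10:20, 1)
    m <- sample(2:3, 1)
    ranks <- sort(sample(N, m))
    sgr <- paste0("s", 1:N)
    gene <- rep("other", N)
    gene[ranks] <- "g"
    map <- data.frame(sgrna = sgr, gene = gene)
    frac <- 0.5
    got <- hypergeom_gene_p(sgr, map, "g", inclusion_fraction = frac)
    cutoff <- floor(frac * N)
    admissible <- which(ranks <= cutoff)
    want <- if (length(admissible) == 0) 1 else
      min(vapply(admissible, function(j)
        enum_hyper_tail(j, m, N, ranks[j]), numeric(1)))
    expect_equal(got, want, tolerance = 1e-10)
  }
})

test_that("spread-out guides and a zero inclusion window give p near 1", {
  map <- data.frame(sgrna = paste0("s", 1:20),
                    gene = c("g", rep("other", 9), "g", rep("other", 9)))
  map$gene[c(1, 11)] <- "other"
  map$gene[c(5, 15)] <- "g"
  p <- hypergeom_gene_p(paste0("s", 1:20), map, "g",
                        inclusion_fraction = 0.5)
  expect_gt(p, 0.3)
  expect_equal(hypergeom_gene_p(paste0("s", 1:20), map, "g",
                                inclusion_fraction = 0), 1)
  expect_error(hypergeom_gene_p(character(0), map, "g"), "empty")
})

test_that("identical arms produce no differentiation dropout hits", {
  sc <- generate_screen(screen_config(seed = 10, n_genes = 80,
                                      n_controls = 40))
  sc$counts[, "control_1"] <- sc$counts[, "initial_1"]
  dd <- differentiation_dropout(sc, "control_1", "initial_1")
  expect_equal(sum(dd$hit != "none"), 0)
})

test_that("planted differentiation-essential genes drop out and are recovered", {
  sc <- generate_screen(screen_config(seed = 12))
  dd <- differentiation_dropout(sc, paste0("control_", 1:3), "initial_1")
  depleted <- dd$gene[dd$hit == "depleted"]
  expect_gte(sum(sc$truth$depletion_genes %in% depleted), 7)
  # their depletion p-values are extreme on the ascending ranking
  planted <- dd[dd$gene %in% sc$truth$depletion_genes, ]
  expect_lt(max(planted$p_deplete), 1e-4)
})

test_that("a null differentiation arm stays clean across seeds", {
  n_hits <- vapply(1:10, function(s) {
    sc <- generate_screen(screen_config(seed = 500 + s, n_genes = 300,
                                        depletion_effect = 1,
                                        rescue_effect = 1))
    dd <- differentiation_dropout(sc, paste0("control_", 1:3), "initial_1")
    sum(dd$hit == "depleted")
  }, numeric(1))
  expect_gte(mean(n_hits == 0), 0.9)
})
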