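test_that("standardization removes bad genes and z-scores the rest", {
  withr::with_seed(2, {
    x <- matrix(rexp(10 * 8, 0.1), 10, 8,
                dimnames = list(paste0("g", 1:10), paste0("s", 1:8)))
  })
  x["g3", ] <- 7                 # constant -> dropped
  x["g5", 1:5] <- NA             # missing in 5/8 > 50% -> dropped
  x["g6", 1:2] <- NA             # 25% missing -> imputed, kept
  out <- standardize_expression(x)
  expect_setequal(attr(out, "dropped"), c("g3", "g5"))
  expect_equal(rowMeans(out), setNames(rep(0, 8), rownames(out)),
               tolerance = 1e-10)
  expect_equal(apply(out, 1, sd), setNames(rep(1, 8), rownames(out)),
               tolerance = 1e-10)
  expect_error(standardize_expression(x[, 1:3]), "4 samples")
})

test_that("soft-threshold scan rejects tiny matrices and scores noise low", {
  two <- matrix(rnorm(8), 2, 4)
  expect_error(pick_soft_threshold(two), "too few genes")
  r2 <- vapply(1:20, function(s) {
    e <- standardize_expression(matrix(withr::with_seed(s, rnorm(60 * 20)),
                                       60, 20,
                                       dimnames = list(paste0("g", 1:60),
                                                       paste0("s", 1:20))),
                                log2_transform = FALSE)
    pick_soft_threshold(e, powers = 1)$sft_r2
  }, numeric(1))
  expect_lt(median(r2), 0.3)   # uncorrelated noise is not scale-free at beta = 1
})

test_that("scale-free fit improves with power on modular expression", {
  sim <- simulate_module_expression(5, 40, 30, within_cor = 0.8, seed = 6)
  e <- standardize_expression(sim$expr, log2_transform = FALSE)
  sft <- pick_soft_threshold(e, powers = c(1, 6, 12, 20))
  expect_true(all(diff(sft$sft_r2) > -0.05))  # monotone up to simulation error
  expect_gt(sft$sft_r2[4], sft$sft_r2[1])
  expect_true(all(diff(sft$mean_k) < 0))      # connectivity shrinks with power
})

test_that("topological overlap matches the hand-computed 3-gene example", {
  a <- matrix(c(1, 0.8, 0.4,
                0.8, 1, 0.2,
                0.4, 0.2, 1), 3, 3, byrow = TRUE)
  tom <- tom_similarity(a)
  # k = (1.2, 1.0, 0.6); e.g. tom_12 = (0.4*0.2 + 0.8)/(1 + 1 - 0.8)
  expect_equal(tom[1, 2], 0.88 / 1.2, tolerance = 1e-12)
  expect_equal(tom[1, 3], 0.56 / 1.2, tolerance = 1e-12)
  expect_equal(tom[2, 3], 0.52 / 1.4, tolerance = 1e-12)
  expect_equal(diag(tom), rep(1, 3))
})

test_that("topological overlap is symmetric and bounded on random adjacencies", {
  for (s in 1:20) {
    n <- withr::with_seed(s, sample(4:12, 1))
    a <- withr::with_seed(s + 100, matrix(runif(n * n), n, n))
    a <- (a + t(a)) / 2
    diag(a) <- 1
    tom <- tom_similarity(a)
    expect_equal(tom, t(tom), tolerance = 1e-12)
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
  }
  # formula limits: a perfectly correlated pair and independent genes
  expect_equal(tom_similarity(matrix(c(1, 1, 1, 1), 2))[1, 2], 1)
  expect_lt(tom_similarity(matrix(c(1, 1e-8, 1e-8, 1), 2))[1, 2], 1e-7)
  expect_error(tom_similarity(matrix(c(1, 2, 0, 1), 2)), "symmetric")
})

test_that("raising the power weakly decreases every off-diagonal adjacency", {
  sim <- simulate_module_expression(3, 20, 15, seed = 3)
  cors <- abs(cor(t(sim$expr)))
  for (b in c(2, 6, 12)) {
    expect_true(all(cors^(b + 1) <= cors^b + 1e-15))
  }
})

test_that("module eigengenes match an independent SVD and align sign", {
  sim <- simulate_module_expression(1, 30, 20, within_cor = 0.6, seed = 9)
  e <- standardize_expression(sim$expr, log2_transform = FALSE)
  mods <- setNames(rep("blue", nrow(e)), rownames(e))
  me <- module_eigengenes(e, mods)
  # oracle: first principal component of the sample x gene matrix
  pc <- prcomp(t(e), center = TRUE, scale. = FALSE)$x[, 1]
  expect_gte(abs(cor(me$eigengenes[, "MEblue"], pc)), 0.999)
  # sign convention: the eigengene always aligns with its module's average
  # profile, so negating every gene gives a deterministic (negated) result
  me_flip <- module_eigengenes(-e, mods)
  expect_equal(abs(cor(me$eigengenes[, 1], me_flip$eigengenes[, 1])), 1,
               tolerance = 1e-10)
  expect_gt(cor(me$eigengenes[, 1], colMeans(e)), 0)
  expect_gt(cor(me_flip$eigengenes[, 1], colMeans(-e)), 0)
  # identical genes: eigengene is the shared profile, variance fully explained
  prof <- e[rep(1, 5), , drop = FALSE]
  rownames(prof) <- paste0("p", 1:5)
  me2 <- module_eigengenes(prof, setNames(rep("red", 5), rownames(prof)))
  expect_equal(me2$var_explained[["MEred"]], 1)
  expect_gte(abs(cor(me2$eigengenes[, 1], prof[1, ])), 1 - 1e-10)
  expect_error(module_eigengenes(e[1, , drop = FALSE],
                                 setNames("x", rownames(e)[1])),
               "fewer than 2")
})

test_that("planted modules are recovered and merged modules stay distinct", {
  sim <- simulate_module_expression(3, 40, 30, within_cor = 0.8, seed = 15)
  e <- standardize_expression(sim$expr, log2_transform = FALSE)
  net <- build_network(e, power = 6, min_module_size = 30)
  ari <- mclust::adjustedRandIndex(net$modules, sim$truth[names(net$modules)])
  expect_gte(ari, 0.9)
  # after merging, no two module eigengenes correlate above the merge cut
  if (ncol(net$eigengenes) >= 2) {
    cc <- cor(net$eigengenes)
    expect_lt(max(cc[upper.tri(cc)]), 0.75)
  }
})

test_that("module-trait association flags matching traits", {
  sim <- simulate_module_expression(2, 35, 15, within_cor = 0.8, seed = 22)
  e <- standardize_expression(sim$expr, log2_transform = FALSE)
  net <- build_network(e, power = 6, min_module_size = 30)
  me <- net$eigengenes
  traits <- cbind(match = me[, 1],
                  ortho = withr::with_seed(5, {
                    r <- rnorm(nrow(me))
                    resid(lm(r ~ me[, 1]))
                  }))
  assoc <- module_trait_association(me, traits,
                                    trait_classes = c(match = "strengthen",
                                                      ortho = "none"))
  m1 <- colnames(me)[1]
  expect_equal(assoc$pcc[m1, "match"], 1, tolerance = 1e-10)
  expect_true(assoc$significant[m1, "match"])
  expect_equal(assoc$pcc[m1, "ortho"], 0, tolerance = 1e-10)
  expect_false(assoc$significant[m1, "ortho"])
  expect_equal(unname(assoc$module_class[m1]), "strengthen-related")
  expect_error(module_trait_association(me, traits[1:5, ]), "match")
})

test_that("noisy coupled traits are detected in most replicates", {
  hits <- vapply(1:50, function(s) {
    withr::with_seed(400 + s, {
      eg <- scale(rnorm(15))[, 1]
      trait <- eg + rnorm(15, 0, 0.3)
    })
    me <- matrix(eg, ncol = 1, dimnames = list(NULL, "MEx"))
    a <- module_trait_association(me, matrix(trait, ncol = 1,
                                             dimnames = list(NULL, "t")))
    a$significant[1, 1]
  }, logical(1))
  expect_gte(mean(hits), 0.9)
})

test_that("hub selection follows the ceiling rule and a sorting oracle", {
  sim <- simulate_module_expression(2, 40, 25, within_cor = 0.7, seed = 31)
  e <- standardize_expression(sim$expr, log2_transform = FALSE)
  net <- build_network(e, power = 6, min_module_size = 30)
  for (m in names(net$hubs)) {
    size <- sum(net$modules == m)
    expect_equal(length(net$hubs[[m]]), ceiling(0.10 * size))
    genes <- names(net$modules)[net$modules == m]
    ord <- genes[order(-net$degree[genes], -net$strength[genes], genes)]
    expect_equal(net$hubs[[m]], ord[seq_along(net$hubs[[m]])])
  }
})

test_that("a star topology yields its center as hub", {
  # build a tiny network object by hand around the exported hub_genes()
  genes <- c("center", paste0("leaf", 1:8))
  net <- list(modules = setNames(rep("blue", 9), genes),
              degree = setNames(c(8, rep(1, 8)), genes),
              strength = setNames(c(8, rep(1, 8)), genes),
              hub_top = 0.10)
  class(net) <- "coexpression_network"
  expect_equal(hub_genes(net), list(blue = "center"))
})

test_that("TMG enrichment fractions and Fisher test behave", {
  genes <- sprintf("g%03d", 1:300)
  modules <- setNames(rep(c("blue", "red", "grey"), each = 100), genes)
  module_class <- c(blue = "weaken-related", red = "other")
  mk_mem <- function(tmg_ids) {
    data.frame(gene_id = genes,
               label = ifelse(genes %in% tmg_ids, "TMG3", "non-responsive"),
               stringsAsFactors = FALSE)
  }
  none <- tmg_module_enrichment(modules, module_class, mk_mem(character(0)))
  expect_equal(none$fractions$fraction, c(0, NA, 0))
  expect_equal(none$fisher_p, 1)
  all_t <- tmg_module_enrichment(modules, module_class, mk_mem(genes))
  expect_equal(all_t$fractions$fraction[c(1, 3)], c(100, 100))
  # Fisher p equals the brute-force hypergeometric tail enumeration
  mem <- mk_mem(c(genes[1:10], genes[101:105]))
  enr <- tmg_module_enrichment(modules, module_class, mem)
  tab <- enr$table
  oracle <- sum(vapply(0:sum(tab[1, ]), function(k) {
    p_k <- dhyper(k, sum(tab[, 1]), sum(tab[, 2]), sum(tab[1, ]))
    if (p_k <= dhyper(tab[1, 1], sum(tab[, 1]), sum(tab[, 2]),
                      sum(tab[1, ])) * (1 + 1e-7)) p_k else 0
  }, numeric(1)))
  expect_equal(enr$fisher_p, oracle, tolerance = 1e-10)
})

test_that("trait replicates map to RNA samples by group means", {
  cfg <- sim_config(n_genes = 50, seed = 2, trait_noise_frac = 0,
                    class_counts = c(tmg3_up = 10))
  sim <- simulate_counts(cfg)
  tr <- simulate_traits(cfg)
  st <- sample_trait_matrix(tr$traits, sim$samples)
  expect_equal(dim(st), c(15, 8))
  b <- cfg$trait_baseline; e <- cfg$trait_effect
  expect_equal(unname(st[sim$samples$group == "CK", "weaken_1"]), rep(b, 3))
  expect_equal(unname(st[sim$samples$group == "S", "weaken_1"]),
               rep(b - e, 3))
  expect_equal(unname(st[sim$samples$group == "P1S-P4S", "strengthen_1"]),
               rep(b + 1.5 * e, 3))
})
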