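test_that("correlation p-values follow the Student-t transformation", {
  x <- 1:10
  expect_equal(cor_with_p(x, x)$r, 1)
  expect_equal(cor_with_p(x, -x)$r, -1)
  expect_error(cor_with_p(x, rep(2, 10)), "constant")
  expect_error(cor_with_p(1:2, 2:1), "n >= 3")

  # independent oracle: p computed directly from the t transformation
  set.seed(71)
  for (rep in 1:20) {
    n <- sample(5:30, 1)
    x <- rnorm(n)
    y <- 0.5 * x + rnorm(n)
    got <- cor_with_p(x, y)
    r <- sum(scale(x) * scale(y)) / (n - 1)
    tval <- r * sqrt(n - 2) / sqrt(1 - r^2)
    expect_equal(got$r, r, tolerance = 1e-12)
    expect_equal(got$p, 2 * pt(abs(tval), n - 2, lower.tail = FALSE),
                 tolerance = 1e-12)
  }
  # the r = 0.5, n = 22 worked case
  set.seed(72)
  x <- rnorm(22)
  y <- rnorm(22)
  y <- as.numeric(scale(residuals(lm(y ~ x)))) * sqrt(1 - 0.25) +
    as.numeric(scale(x)) * 0.5
  got <- cor_with_p(x, y)
  expect_equal(got$r, 0.5, tolerance = 1e-10)
  expect_equal(got$p, 2 * pt(0.5 * sqrt(20) / sqrt(0.75), 20,
                             lower.tail = FALSE), tolerance = 1e-10)
})

test_that("module eigengene matches the first principal component", {
  # rank-1 module: identical genes recover the z-scored common profile
  prof <- rnorm(15)
  expr <- rbind(a = prof, b = 2 * prof + 3, c = -prof)
  colnames(expr) <- paste0("s", 1:15)
  eg <- module_eigengene(expr, c("a", "b", "c"))
  expect_equal(eg$var_explained, 1, tolerance = 1e-12)
  expect_equal(abs(cor(eg$eigengene, prof)), 1, tolerance = 1e-12)
  expect_equal(sd(eg$eigengene), 1, tolerance = 1e-12)
  # sign aligned with the module mean profile
  expect_gt(cor(eg$eigengene, colMeans(t(scale(t(expr))))), 0)

  # generic PCA oracle on 50 random modules
  set.seed(73)
  for (rep in 1:50) {
    g <- sample(3:20, 1)
    n <- sample(8:25, 1)
    m <- random_expr(g, n)
    eg <- module_eigengene(m, rownames(m))
    pc <- prcomp(t(t(scale(t(m)))), center = TRUE)
    expect_gte(abs(cor(eg$eigengene, pc$x[, 1])), 0.999)
  }
})

test_that("eigengenes recover planted module factors", {
  cfg <- sim_config(module_sizes = 30L, within_module_cor = 0.9,
                    trait_effect = 0, n_hubs = 0L, n_background_genes = 0L,
                    seed = 75)
  sim <- simulate_expression(cfg)
  eg <- module_eigengene(sim$expr, rownames(sim$expr))
  expect_gte(abs(cor(eg$eigengene, sim$truth$factors[, 1])), 0.95)
})

test_that("module significance separates trait modules from null modules", {
  # null module: MS near the null mean of |r| at this sample size
  n <- 22
  null_ms <- vapply(1:200, function(s) {
    cfg <- sim_config(module_sizes = 30L, within_module_cor = 0.7,
                      trait_effect = 0, n_hubs = 0L,
                      n_background_genes = 0L, seed = s)
    sim <- simulate_expression(cfg)
    trait <- stage_trait(sim$stages)
    mean(abs(cor(t(sim$expr), trait$z)))
  }, numeric(1))
  expect_lt(abs(mean(null_ms) - sqrt(2 / (pi * (n - 1)))),
            0.5 * sqrt(2 / (pi * (n - 1))))

  # planted trait module beats a null module almost always
  wins <- vapply(1:100, function(s) {
    cfg <- sim_config(module_sizes = c(40L, 40L),
                      within_module_cor = c(0.7, 0.7),
                      trait_effect = c(-0.8, 0), n_hubs = c(0L, 0L),
                      n_background_genes = 0L, seed = s)
    sim <- simulate_expression(cfg)
    trait <- stage_trait(sim$stages)
    ms <- module_significance(sim$expr, trait, sim$truth$module)
    ms$MS[ms$module == 1] > ms$MS[ms$module == 2]
  }, logical(1))
  expect_gte(mean(wins), 0.95)

  # genes identical to +/- trait give MS = 1
  z <- stage_trait(factor(rep(c("a", "b", "c", "d"), each = 3),
                          levels = c("a", "b", "c", "d")))
  expr <- rbind(g1 = z$z, g2 = -z$z)
  colnames(expr) <- paste0("s", 1:12)
  labels <- c(g1 = 1L, g2 = 1L)
  suppressWarnings(ms <- module_significance(expr, z, labels))
  expect_equal(ms$MS[ms$module == 1], 1, tolerance = 1e-12)
})

test_that("module selection prefers MS, checks the eigengene criterion, breaks ties low", {
  single <- data.frame(module = c(0L, 1L), size = c(10L, 40L),
                       MS = c(0.2, 0.5), me_trait_r = c(NA, -0.7),
                       me_trait_p = c(NA, 0.001))
  expect_equal(as.integer(select_significant_module(single)), 1L)

  tie <- data.frame(module = 1:2, size = c(50L, 40L), MS = c(0.5, 0.5),
                    me_trait_r = c(-0.8, -0.3), me_trait_p = c(0.01, 0.2))
  expect_warning(sel <- select_significant_module(tie), "tie")
  expect_equal(as.integer(sel), 1L)

  disagree <- data.frame(module = 1:2, size = c(50L, 40L), MS = c(0.6, 0.4),
                         me_trait_r = c(-0.5, -0.9),
                         me_trait_p = c(0.05, 0.001))
  expect_warning(sel2 <- select_significant_module(disagree), "disagree|MS criterion")
  expect_equal(as.integer(sel2), 1L)
  expect_false(attr(sel2, "agree"))

  # planted design: both criteria agree on the trait module in >= 18/20 seeds
  hits <- vapply(1:20, function(s) {
    cfg <- sim_config(trait_effect = c(-0.75, 0, 0), n_hubs = c(0L, 0L, 0L),
                      seed = s)
    sim <- simulate_expression(cfg)
    trait <- stage_trait(sim$stages)
    ms <- module_significance(sim$expr, trait, sim$truth$module)
    sel <- select_significant_module(ms)
    as.integer(sel) == 1L && attr(sel, "agree")
  }, logical(1))
  expect_gte(sum(hits), 18)
})

test_that("screening blends gene and eigengene profiles as configured", {
  sim <- simulate_expression(sim_config(n_hubs = c(3L, 0L, 0L), seed = 77))
  trait <- stage_trait(sim$stages)
  labels <- sim$truth$module
  eg <- module_eigengenes(sim$expr, labels)
  sc0 <- screening_stats(sim$expr, trait, eg, labels, mix_weight = 0)
  expect_equal(sc0$table$cor.Weighted, sc0$table$cor.Standard,
               tolerance = 1e-12)

  sc <- screening_stats(sim$expr, trait, eg, labels, mix_weight = 0.5)
  # grey genes never blend
  grey <- sc$table$module == 0
  expect_equal(sc$table$cor.Weighted[grey], sc$table$cor.Standard[grey],
               tolerance = 1e-12)
  # kME of a module gene against its own eigengene is high at rho = 0.7
  own <- sc$table$module == 1
  expect_gt(mean(abs(sc$kME[own, "ME1"])), 0.7)

  # a gene identical to its module eigengene: blending changes nothing
  expr2 <- rbind(sim$expr, ghost = eg$eigengenes[, "ME1"])
  labels2 <- c(labels, ghost = 1L)
  sc2 <- screening_stats(expr2, trait, module_eigengenes(expr2, labels2),
                         labels2)
  row <- sc2$table[sc2$table$gene == "ghost", ]
  expect_lt(abs(row$cor.Weighted - row$cor.Standard), 0.02)

  # eigengene averaging denoises ordinary module genes: their own trait
  # correlation is noisier than the eigengene's, so blending usually helps
  gains <- vapply(1:100, function(s) {
    cfg <- sim_config(module_sizes = 40L, within_module_cor = 0.7,
                      trait_effect = -0.75, n_hubs = 3L, hub_trait_cor = 0.85,
                      n_background_genes = 0L, seed = s)
    sm <- simulate_expression(cfg)
    tr <- stage_trait(sm$stages)
    lb <- sm$truth$module
    s2 <- screening_stats(sm$expr, tr, module_eigengenes(sm$expr, lb), lb)
    ordinary <- !(s2$table$gene %in% sm$truth$hubs)
    mean(abs(s2$table$cor.Weighted[ordinary]) >=
           abs(s2$table$cor.Standard[ordinary]))
  }, numeric(1))
  expect_gte(mean(gains), 0.8)
})

test_that("hub selection applies the strict dual-threshold rule", {
  tab <- data.frame(
    gene = c("h1", "h2", "h3", "half", "edge", "out"),
    module = c(1L, 1L, 1L, 1L, 1L, 2L),
    cor.Standard = c(-0.806, -0.802, 0.881, 0.79, 0.80, 0.95),
    p.Standard = 0.001,
    cor.Weighted = c(-0.948, -0.931, 0.944, 0.948, 0.80, 0.95),
    p.Weighted = 0.001, stringsAsFactors = FALSE)
  hubs <- identify_hubs(tab, module = 1, threshold = 0.8)
  expect_setequal(hubs$gene, c("h1", "h2", "h3"))   # dual rule passes all 3
  expect_false("half" %in% hubs$gene)               # one criterion fails
  expect_false("edge" %in% hubs$gene)               # strict inequality
  expect_false("out" %in% hubs$gene)                # other module
  expect_equal(hubs$gene[1], "h1")                  # sorted by |cor.Weighted|
  expect_equal(nrow(identify_hubs(tab, module = 3)), 0L)
})

test_that("planted hubs are recovered with high sensitivity and specificity", {
  # hub-coherent design: the hub module's factor tracks the trait as strongly
  # as the hubs themselves; non-hub metric genes have construction |r| <= 0.4
  stats <- t(vapply(1:50, function(s) {
    cfg <- sim_config(trait_effect = c(-0.85, 0, 0), n_hubs = c(3L, 0L, 0L),
                      hub_trait_cor = 0.85, seed = s)
    sim <- simulate_expression(cfg)
    trait <- stage_trait(sim$stages)
    labels <- sim$truth$module
    sc <- screening_stats(sim$expr, trait,
                          module_eigengenes(sim$expr, labels), labels)
    hubs <- identify_hubs(sc, module = 1)
    planted <- sim$truth$hubs
    low_cor <- names(labels)[labels != 1]
    c(sens = mean(planted %in% hubs$gene),
      spec = mean(!low_cor %in% hubs$gene))
  }, c(sens = 0, spec = 0)))
  expect_gte(mean(stats[, "sens"]), 0.9)
  expect_gte(mean(stats[, "spec"]), 0.95)
})

test_that("stage ANOVA matches hand computation and handles degeneracies", {
  expr <- matrix(c(1, 2, 2, 3, 4, 5), nrow = 1,
                 dimnames = list("g1", paste0("s", 1:6)))
  stages <- factor(rep(c("a", "b", "c"), each = 2), levels = c("a", "b", "c"))
  res <- stage_anova(expr, stages)
  # group means 1.5 / 2.5 / 4.5, SSB = 28/3, SSW = 1.5, df (2, 3)
  expect_equal(res$F, (28 / 3 / 2) / (1.5 / 3), tolerance = 1e-12)
  expect_equal(res$p, pf(res$F, 2, 3, lower.tail = FALSE), tolerance = 1e-12)
  # cross-check against the standard linear-model ANOVA
  fit <- anova(lm(as.numeric(expr) ~ stages))
  expect_equal(res$F, fit$`F value`[1], tolerance = 1e-12)
  expect_equal(res$p, fit$`Pr(>F)`[1], tolerance = 1e-12)

  # identical group means: F = 0, p = 1
  e0 <- matrix(rep(c(1, 2, 3), 2), nrow = 1,
               dimnames = list("g", paste0("s", 1:6)))
  r0 <- stage_anova(e0, factor(rep(c("a", "b"), each = 3)))
  expect_equal(r0$F, 0)
  expect_equal(r0$p, 1)

  # zero within-group variance with distinct means: p at the floor
  ed <- matrix(c(1, 1, 1, 2, 2, 2), nrow = 1,
               dimnames = list("g", paste0("s", 1:6)))
  rd <- stage_anova(ed, factor(rep(c("a", "b"), each = 3)))
  expect_true(is.infinite(rd$F))
  expect_equal(rd$p, 2.2e-16)

  # a stage with fewer than 2 samples is an error naming the stage
  expect_error(stage_anova(expr, factor(c("a", "a", "b", "b", "c", "d"))),
               "c, d|d")
  # the 7/6/6/3 design passes
  sim <- simulate_expression(sim_config(seed = 79))
  expect_silent(stage_anova(sim$expr[1:5, ], sim$stages))
})

test_that("flipping the trait coding flips correlations but not decisions", {
  sim <- simulate_expression(sim_config(n_hubs = c(3L, 0L, 0L), seed = 81))
  labels <- sim$truth$module
  fwd <- stage_trait(sim$stages)
  rev <- stage_trait(factor(sim$stages,
                            levels = rev(levels(sim$stages))))
  eg <- module_eigengenes(sim$expr, labels)
  sc_f <- screening_stats(sim$expr, fwd, eg, labels)
  sc_r <- screening_stats(sim$expr, rev, eg, labels)
  expect_equal(sc_f$table$cor.Standard, -sc_r$table$cor.Standard,
               tolerance = 1e-12)
  expect_equal(sc_f$table$cor.Weighted, -sc_r$table$cor.Weighted,
               tolerance = 1e-12)
  ms_f <- module_significance(sim$expr, fwd, labels, eg)
  ms_r <- module_significance(sim$expr, rev, labels, eg)
  expect_equal(ms_f$MS, ms_r$MS, tolerance = 1e-12)
  expect_equal(abs(ms_f$me_trait_r), abs(ms_r$me_trait_r), tolerance = 1e-12)
  expect_setequal(identify_hubs(sc_f, 1)$gene, identify_hubs(sc_r, 1)$gene)

  # internal consistency: MS equals the mean |cor.Standard| per module
  for (m in 1:3) {
    expect_equal(ms_f$MS[ms_f$module == m],
                 mean(abs(sc_f$table$cor.Standard[sc_f$table$module == m])),
                 tolerance = 1e-12)
  }
})
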