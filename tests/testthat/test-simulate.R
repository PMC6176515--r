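test_that("effective positive-gene guide effects have marginal SD 1.25", {
  # analytic: sqrt(gene_effect_sd^2 + guide_noise_sd^2)
  expect_equal(sqrt(0.75^2 + 1^2), 1.25)
  sim <- simulate_screen(n_genes_null = 0, n_genes_pos = 20000,
                         guides_per_gene = 5, efficiency = 1,
                         n_controls = 10, seed = 81)
  eff <- sim$truth$guide_effective == 1
  x <- sim$guides$lfc[!sim$guides$control][
    eff[!sim$guides$control]]
  expect_gt(length(x), 9e4)
  expect_equal(sd(x), 1.25, tolerance = 0.01)
  expect_equal(mean(x), -3, tolerance = 0.01)
})

test_that("zero efficiency makes positive-gene guides null", {
  sim <- simulate_screen(n_genes_null = 0, n_genes_pos = 2000,
                         guides_per_gene = 5, efficiency = 0,
                         n_controls = 10, seed = 82)
  x <- sim$guides$lfc[!sim$guides$control]
  ref <- rskewt(1e4, 0, 1, -1.5, 6, seed = 83)
  ks <- suppressWarnings(ks.test(x, ref))
  expect_gt(ks$p.value, 0.01)
  expect_true(all(sim$truth$guide_effective == 0))
})

test_that("simulation is reproducible under a fixed seed", {
  a <- simulate_screen(100, 20, 4, 0.5, n_controls = 50, seed = 84)
  b <- simulate_screen(100, 20, 4, 0.5, n_controls = 50, seed = 84)
  expect_identical(a, b)
  c <- simulate_screen(100, 20, 4, 0.5, n_controls = 50, seed = 85)
  expect_false(identical(a$guides$lfc, c$guides$lfc))
})

test_that("truth labels are hierarchy-consistent", {
  sim <- simulate_screen(200, 100, 6, 0.4, n_controls = 50, seed = 86)
  g <- sim$guides
  truth <- sim$truth
  z <- truth$genes$interesting[match(g$gene, truth$genes$gene)]
  y <- truth$guide_effective
  # no effective guide in a null gene, and controls are never effective
  expect_true(all(y[!g$control][z[!g$control] == 0] == 0))
  expect_true(all(y[g$control] == 0))
  # effective fraction among positive-gene guides matches efficiency
  pos <- !g$control & z == 1
  phat <- mean(y[pos])
  expect_lt(abs(phat - 0.4), 3 * sqrt(0.4 * 0.6 / sum(pos)))
  expect_error(simulate_screen(10, 5, 3, efficiency = 1.2), "efficiency")
})

test_that("semi-simulated guides per gene follow NB(mu = 67.8, r = 26.3)", {
  set.seed(87)
  draws <- stats::rnbinom(1e4, mu = 67.8, size = 26.3)
  # the generator redraws zeros; at this mu zeros are essentially absent
  sim <- simulate_semisim(n_pos_genes = 40, null_per_pos = 3, seed = 88)
  gene <- sim$counts$gene_id
  null_genes <- grepl("^nullsim_", gene)
  sizes <- table(gene[null_genes])
  expect_equal(length(sizes), 120) # 3 null genes per positive gene
  expect_equal(mean(sizes), 67.8, tolerance = 0.05 * 67.8)
  expect_true(all(sizes >= 1))
  # positive fraction of the simulated design is 0.25
  tg <- sim$truth$genes
  expect_equal(mean(tg$interesting), 0.25)
})

test_that("semi-simulated counts have NB(size = 200) variance", {
  set.seed(89)
  c0 <- 150
  draws <- stats::rnbinom(1e5, mu = c0, size = 200)
  expect_equal(var(draws), c0 + c0^2 / 200, tolerance = 0.05 * (c0 + c0^2 / 200))
  expect_equal(mean(draws), c0, tolerance = 1)
})

test_that("semi-simulated screen runs through the count pipeline", {
  sim <- simulate_semisim(n_pos_genes = 10, seed = 90)
  expect_s3_class(sim$counts, "count_matrix")
  gt <- compute_lfc(sim$counts, "initial", "final")
  expect_true(sum(gt$control) > 0)
  # null-gene guides mirror the control distribution; positives deplete
  tg <- sim$truth$genes
  z <- tg$interesting[match(gt$gene, tg$gene)]
  expect_lt(mean(gt$lfc[!gt$control][z[!gt$control] == 1]),
            mean(gt$lfc[!gt$control][z[!gt$control] == 0]))
})

test_that("simulate -> fit round trip recovers the generative tau", {
  # tau = p * q when every gene has the same number of guides
  for (s in c(201, 204)) {
    sim <- simulate_screen(n_genes_null = 1500, n_genes_pos = 150,
                           guides_per_gene = 8, efficiency = 0.9,
                           n_controls = 100, seed = s)
    x <- sim$guides$lfc[!sim$guides$control]
    fit <- em_mixture(x, null_fit = true_skewt_null())
    expect_lt(abs(fit$tau - 150 / 1650 * 0.9), 0.03)
  }
})

test_that("downsampling hits the target average and keeps controls", {
  sim <- simulate_screen(n_genes_null = 150, n_genes_pos = 50,
                         guides_per_gene = 20, efficiency = 0.5,
                         n_controls = 100, seed = 91)
  reps <- downsample_library(sim$guides, target_mean_guides = 5,
                             n_reps = 20, seed = 92)
  means <- vapply(reps, function(r) {
    mean(table(r$gene[!r$control]))
  }, numeric(1))
  expect_lt(abs(mean(means) - 5), 0.5)
  expect_true(all(vapply(reps, function(r) sum(r$control), numeric(1))
                  == 100))
  # target equal to the current mean is the identity up to ordering
  full <- downsample_library(sim$guides, 20, n_reps = 1, seed = 93)[[1]]
  expect_setequal(full$guide, sim$guides$guide)
  expect_error(downsample_library(sim$guides, 25), "exceeds")
  # fixed seed reproduces the replicate sets exactly
  reps2 <- downsample_library(sim$guides, 5, n_reps = 20, seed = 92)
  expect_identical(reps, reps2)
})
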