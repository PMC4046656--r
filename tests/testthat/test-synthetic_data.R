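test_that("simulation is deterministic and stable under gene addition", {
  cfg <- sim_config(n_genes = 30, seed = 5)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1, d2)

  td <- withr::local_tempdir()
  write_sim_dataset(d1, file.path(td, "a"))
  write_sim_dataset(d2, file.path(td, "b"))
  for (f in list.files(file.path(td, "a")))
    expect_identical(readLines(file.path(td, "a", f)),
                     readLines(file.path(td, "b", f)))

  # enlarging n_genes must not reshuffle the structure of earlier genes
  d3 <- simulate_dataset(sim_config(n_genes = 40, seed = 5))
  expect_identical(d3$truth$isotigs[1:30], d1$truth$isotigs)
  expect_identical(d3$truth$contigs[1:30], d1$truth$contigs)
  expect_identical(d3$catalog$description[1:30], d1$catalog$description)
})

test_that("truth manifest respects nulls, exclusives and normalization", {
  d0 <- simulate_dataset(sim_config(n_genes = 50, de_fraction = 0, seed = 2))
  expect_true(all(d0$truth$true_logFC == 0))
  expect_false(any(d0$truth$is_de))

  d <- simulate_dataset(sim_config(n_genes = 60, de_fraction = 0.3,
                                   exclusive_fraction = 0.5, seed = 3))
  tr <- d$truth
  expect_equal(sum(tr$p_fruit), 1, tolerance = 1e-12)
  expect_equal(sum(tr$p_az), 1, tolerance = 1e-12)
  expect_true(all(tr$true_logFC[!tr$is_de] == 0))
  # exclusive genes: zero abundance on one side and exactly zero reads there
  exc <- tr[tr$is_exclusive, ]
  expect_true(all(exc$p_fruit == 0 | exc$p_az == 0))
  expect_true(all(exc$y_fruit[exc$p_fruit == 0] == 0))
  expect_true(all(exc$y_az[exc$p_az == 0] == 0))

  # library totals: sum over contigs equals sum of gene-level draws
  expect_equal(sum(d$assembly$contigs$reads_fruit), sum(tr$y_fruit))
  expect_equal(sum(d$assembly$contigs$reads_az), sum(tr$y_az))

  # every isotig gets a sub-threshold true hit; decoys all sit above it
  best <- assign_best_hit(filter_hits(d$hits))
  expect_setequal(best$isotig_id, names(d$assembly$isotigs))
  decoys <- d$hits[d$hits$evalue >= 1e-20, ]
  expect_true(all(decoys$evalue >= 1e-20))
})

test_that("null counts are Poisson-dispersed when phi is zero", {
  ratios <- vapply(1:3, function(s) {
    d <- simulate_dataset(sim_config(n_genes = 200, phi = 0,
                                     de_fraction = 0, seed = s))
    y1 <- d$truth$y_fruit; y2 <- d$truth$y_az
    sum((y1 - y2)^2) / sum(y1 + y2)
  }, numeric(1L))
  # (Y1-Y2)^2 has expectation Y1+Y2 under equal-mean Poisson pairs;
  # band = 4 MC standard errors of the per-dataset ratio
  expect_true(all(abs(ratios - 1) < 0.6))
  expect_lt(abs(mean(ratios) - 1), 0.3)
})

test_that("stronger effects never weaken the estimated fold changes", {
  mean_abs_lfc <- function(effect) {
    d <- simulate_dataset(sim_config(n_genes = 100, logfc_effect = effect,
                                     exclusive_fraction = 0, seed = 7))
    tr <- d$truth
    N1 <- sum(tr$y_fruit); N2 <- sum(tr$y_az)
    est <- log_fold_change(tr$y_fruit, tr$y_az, N1, N2)
    mean(abs(est[tr$is_de]))
  }
  vals <- vapply(c(0.5, 1, 2, 3), mean_abs_lfc, numeric(1L))
  expect_true(all(diff(vals) >= 0))
})

test_that("truth_eval scores callers against the manifest", {
  d <- simulate_dataset(sim_config(n_genes = 10, de_fraction = 0.4, seed = 4))
  tr <- d$truth
  perfect <- data.frame(unigene_id = tr$unigene_id,
                        significant = tr$is_de,
                        logFC = tr$true_logFC, stringsAsFactors = FALSE)
  ev <- truth_eval(perfect, tr)
  expect_equal(unname(ev$confusion[c("FP", "FN")]), c(0L, 0L))
  expect_equal(ev$tpr, 1)
  expect_equal(ev$logfc_bias, 0)

  nothing <- perfect; nothing$significant <- FALSE
  ev0 <- truth_eval(nothing, tr)
  expect_equal(unname(ev0$confusion["TP"]), 0L)
  expect_equal(unname(ev0$confusion["FN"]), sum(tr$is_de))

  bad <- perfect; bad$unigene_id[1] <- "nope"
  expect_error(truth_eval(bad, tr), "nope")

  # a random caller at rate r on nulls yields FP rate ~ r (binomial band)
  d2 <- simulate_dataset(sim_config(n_genes = 400, de_fraction = 0, seed = 6))
  set.seed(1)
  r <- 0.2
  calls <- data.frame(unigene_id = d2$truth$unigene_id,
                      significant = runif(400) < r,
                      logFC = 0, stringsAsFactors = FALSE)
  ev2 <- truth_eval(calls, d2$truth)
  expect_lt(abs(ev2$fpr - r), 4 * sqrt(r * (1 - r) / 400))
})
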