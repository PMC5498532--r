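test_that("generation is deterministic given the seed", {
  p <- small_params(seed = 11)
  a <- simulate_cell_lines(p)
  b <- simulate_cell_lines(p)
  expect_identical(a$expr$values, b$expr$values)
  expect_identical(a$truth$sample_state, b$truth$sample_state)
  ta <- simulate_bulk_tumors(p)
  tb <- simulate_bulk_tumors(p)
  expect_identical(ta$expr$values, tb$expr$values)
  expect_identical(as.data.frame(ta$clinical), as.data.frame(tb$clinical))
  # different seeds give different draws
  expect_false(identical(simulate_cell_lines(small_params(seed = 12))$expr$values,
                         a$expr$values))
})

test_that("cell-line sub-stream is independent of the tumor stage", {
  p <- small_params(seed = 5)
  a <- simulate_cell_lines(p)
  invisible(simulate_bulk_tumors(p)) # must not perturb the other stage
  b <- simulate_cell_lines(p)
  expect_identical(a$expr$values, b$expr$values)
})

test_that("planted shifts hit their nominal size in the no-noise limit", {
  p <- small_params(seed = 3, noise_sd = 1e-9, effect_size = 2)
  cl <- simulate_cell_lines(p)
  st <- cl$truth$sample_state
  roles <- cl$truth$gene_role
  for (g in names(roles)[roles == "epi_marker"][1:3]) {
    d <- mean(cl$expr$values[g, st == "epithelial"]) -
      mean(cl$expr$values[g, st == "mesenchymal"])
    expect_equal(d, 2.0, tolerance = 1e-6)
  }
  nul <- names(roles)[roles == "null"][1]
  expect_equal(mean(cl$expr$values[nul, st == "epithelial"]) -
                 mean(cl$expr$values[nul, st == "mesenchymal"]),
               0, tolerance = 1e-6)
})

test_that("anchor construction makes the 10-fold rule classify every line", {
  cl <- simulate_cell_lines(sim_params(seed = 1))
  calls <- quiet(classify_cell_lines(cl$expr))
  expect_equal(mean(calls$state != "ambiguous"), 1.0)
  truth_state <- cl$truth$sample_state[calls$sample_id]
  expect_true(all((calls$state == "epithelial_like") ==
                    (truth_state == "epithelial")))
})

test_that("tumors at purity 1 carry no stromal term and stay non-negative", {
  p <- small_params(seed = 2, purity_range = c(1, 1), noise_sd = 1e-9)
  tu <- simulate_bulk_tumors(p)
  roles <- tu$truth$gene_role
  # null genes reduce to their flat baseline
  nul <- names(roles)[roles == "null"][1:5]
  for (g in nul) expect_lt(sd(tu$expr$values[g, ]) / mean(tu$expr$values[g, ]), 1e-6)
  # VIM stays within its cancer-cell dynamic range (no 30x stromal inflation)
  expect_lt(max(tu$expr$values["VIM", ]), 2^(7 + p$effect_size) * 1.01)
  expect_true(all(simulate_bulk_tumors(small_params(seed = 4))$expr$values >= 0))
})

test_that("null genes stay uncorrelated with VIM under contamination", {
  tu <- simulate_bulk_tumors(small_params(seed = 6))
  roles <- tu$truth$gene_role
  ents <- unique(unname(tu$expr$entity))
  ids <- names(tu$expr$entity)[tu$expr$entity == ents[1]]
  m <- tu$expr$values[, ids]
  r <- cor(t(m[names(roles)[roles == "null"], ]), m["VIM", ],
           method = "spearman")[, 1]
  expect_lt(abs(mean(r)), 0.05)
  expect_lt(max(abs(r)), 0.3)
})

test_that("outcome links point the right way", {
  tu <- simulate_bulk_tumors(sim_params(seed = 8))
  cli <- as.data.frame(tu$clinical)
  e <- tu$truth$emt_score[cli$sample_id]
  # M1 and N+ are enriched at high EMT score
  expect_gt(mean(e[cli$m_status == "M1"]), mean(e[cli$m_status == "M0"]))
  expect_gt(mean(e[cli$n_status == "Nplus"]), mean(e[cli$n_status == "N0"]))
  # CMS4 pseudo-subtype is the most mesenchymal quartile
  expect_equal(names(which.max(tapply(e, cli$subtype, mean))), "CMS4")
  # censoring is in the neighbourhood of the target rate
  expect_equal(1 - mean(cli$os_event), 0.2, tolerance = 0.05)
  # higher EMT shortens observed event times on average
  ev <- cli$os_event == 1
  expect_lt(cor(e[ev], cli$os_time[ev]), 0)
})

test_that("raising the effect size cannot hurt cell-line marker recovery", {
  recovery <- sapply(c(0.5, 1.0, 2.0), function(es) {
    p <- small_params(seed = 9, effect_size = es)
    cl <- simulate_cell_lines(p)
    res <- quiet(cell_line_screen(cl$expr))
    roles <- cl$truth$gene_role
    mean(names(roles)[roles == "epi_marker"] %in% res$signature$epithelial)
  })
  expect_true(all(diff(recovery) >= 0))
  expect_equal(recovery[3], 1.0)
})

test_that("null survival link is calibrated", {
  # hazard_ratio_mes = 1: low/high-EMT halves come from the same exponential
  rej <- sapply(1:400, function(s) {
    p <- sim_params(n_tumor_entities = 1, n_tumors_per_entity = 60,
                    n_epi_markers = 0, n_mes_markers = 0,
                    n_entity_specific = 0, n_null = 1,
                    hazard_ratio_mes = 1, censor_rate = 0, seed = s)
    tu <- simulate_bulk_tumors(p)
    cli <- as.data.frame(tu$clinical)
    e <- tu$truth$emt_score[cli$sample_id]
    hi <- e > median(e)
    logrank_test(cli$os_time[!hi], cli$os_event[!hi],
                 cli$os_time[hi], cli$os_event[hi])$p_value < 0.05
  })
  expect_gt(mean(rej), 0.02)
  expect_lt(mean(rej), 0.08)
})

test_that("parameter invariants are enforced", {
  expect_error(sim_params(noise_sd = 0), "noise_sd")
  expect_error(sim_params(purity_range = c(0, 1)), "purity_range")
  expect_error(sim_params(stroma_factor_range = c(0.5, 10)), "stroma_factor_range")
  expect_error(sim_params(censor_rate = 1), "censor_rate")
})
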