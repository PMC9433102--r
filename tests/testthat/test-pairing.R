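test_that("single-alpha fraction counts distinct alpha clonotypes per cell", {
  sc <- simulate_paired_sc(200, dual_alpha_fraction = 0, seed = 1)
  expect_equal(as.numeric(single_alpha_fraction(sc)), 1.0)
  # 87 of 100 single-alpha
  sc2 <- simulate_paired_sc(100, dual_alpha_fraction = 0, seed = 2)
  dual_cells <- unique(sc2$cell_id)[1:13]
  alpha_rows <- sc2[sc2$chain == "alpha" & sc2$cell_id %in% dual_cells, ]
  alpha_rows$junction <- paste0("TGTAAA", alpha_rows$junction)  # new clonotype
  alpha_rows$junction_aa <- tcrlong:::translate_nt(alpha_rows$junction)
  expect_equal(as.numeric(single_alpha_fraction(dplyr::bind_rows(sc2, alpha_rows))),
               0.87)
})

test_that("cells without an alpha chain are excluded with a warning", {
  sc <- simulate_paired_sc(50, dual_alpha_fraction = 0, seed = 3)
  broken <- sc[!(sc$cell_id == sc$cell_id[1] & sc$chain == "alpha"), ]
  expect_warning(f <- single_alpha_fraction(broken), "no TCR alpha")
  expect_equal(attr(f, "n_excluded"), 1L)
  expect_equal(as.numeric(f), 1.0)
})

test_that("recovered single-alpha fraction sits in the binomial interval", {
  sc <- simulate_paired_sc(50000, dual_alpha_fraction = 0.154, seed = 4)
  f <- single_alpha_fraction(sc)
  se <- sqrt(0.846 * 0.154 / 50000)
  expect_lt(abs(f - 0.846), 4 * se)
})

test_that("small samples merge greedily with cell conservation", {
  mk_sc <- function(n, seed) simulate_paired_sc(n, 0, seed = seed)
  big <- list(A = mk_sc(2500, 5), B = mk_sc(3000, 6))
  expect_identical(names(merge_small_samples(big, min_cells = 2000)),
                   c("A", "B"))
  small <- list(A = mk_sc(900, 7), B = mk_sc(1500, 8))
  merged <- merge_small_samples(small, min_cells = 2000)
  expect_length(merged, 1)
  expect_equal(length(unique(merged[[1]]$cell_id)), 2400)
  # a lone undersized sample passes through as the residual
  lone <- merge_small_samples(list(A = mk_sc(100, 9)), min_cells = 2000)
  expect_length(lone, 1)
  expect_equal(length(unique(lone[[1]]$cell_id)), 100)
  # mixed: big samples untouched, small ones pooled
  mixed <- merge_small_samples(list(A = mk_sc(2500, 10), B = mk_sc(800, 11),
                                    C = mk_sc(1400, 12)), min_cells = 2000)
  expect_length(mixed, 2)
  totals <- vapply(mixed, function(s) length(unique(s$cell_id)), integer(1))
  expect_equal(sum(totals), 2500 + 800 + 1400)
})

test_that("through-origin slope matches the closed form sum(xy)/sum(x^2)", {
  # y = 0.1 x exactly
  exact <- tibble::tibble(alpha_unique = c(100, 200, 300), beta_unique = 0,
                          paired_unique = NA)
  f <- 1
  x <- f * exact$alpha_unique + exact$beta_unique
  exact$paired_unique <- 0.1 * x + pmax(f * exact$alpha_unique, exact$beta_unique)
  m <- fit_pairing_model(exact, f = 1)
  expect_equal(m$M, 0.1, tolerance = 1e-12)
  # hand-computed two-point fit: x = (10, 20), y = (1.5, 2.5)
  # M = (10*1.5 + 20*2.5) / (100 + 400) = 65/500 = 0.13
  two <- tibble::tibble(alpha_unique = c(10, 20), beta_unique = 0,
                        paired_unique = c(1.5 + 10, 2.5 + 20))
  expect_equal(fit_pairing_model(two, f = 1)$M, 0.13, tolerance = 1e-12)
  # one sample: M = y/x
  one <- tibble::tibble(alpha_unique = 10, beta_unique = 0,
                        paired_unique = 12)
  expect_equal(fit_pairing_model(one, f = 1)$M, 0.2, tolerance = 1e-12)
  expect_error(fit_pairing_model(
    tibble::tibble(alpha_unique = 0, beta_unique = 0, paired_unique = 0),
    f = 1), "zero")
})

test_that("pairing equations reproduce the lineage worked examples", {
  # CD4: 0.138 x (0.870*1000 + 1000) + max(0.870*1000, 1000) = 1258.06
  expect_equal(apply_pairing_equation(pairing_model_cd4(), 1000, 1000),
               1258.06, tolerance = 1e-9)
  # CD8: 0.035 x (0.846*1000 + 1000) + max(0.846*1000, 1000) = 1064.61
  expect_equal(apply_pairing_equation(pairing_model_cd8(), 1000, 1000),
               1064.61, tolerance = 1e-9)
  # zero-alpha boundary: 0.138*500 + 500 = 569
  expect_equal(apply_pairing_equation(pairing_model_cd4(), 0, 500), 569)
  expect_error(apply_pairing_equation(pairing_model_cd4(), -1, 10),
               "non-negative")
})

test_that("paired projections dominate both unpaired richness values", {
  set.seed(13)
  for (model in list(pairing_model_cd4(), pairing_model_cd8())) {
    a <- runif(2000, 0, 1e6)
    b <- runif(2000, 0, 1e6)
    paired <- apply_pairing_equation(model, a, b)
    expect_true(all(paired >= pmax(model$f * a, b)))
  }
})

test_that("the pairing equation is homogeneous of degree 1", {
  set.seed(14)
  model <- pairing_model_cd4()
  a <- runif(200, 0, 1e5); b <- runif(200, 0, 1e5)
  c_scale <- runif(200, 0.1, 10)
  expect_equal(apply_pairing_equation(model, c_scale * a, c_scale * b),
               c_scale * apply_pairing_equation(model, a, b),
               tolerance = 1e-9)
})

test_that("fit recovers known (M, f) from simulated summaries and cells", {
  samples <- simulate_pairing_samples(25, M = 0.12, f = 0.87,
                                      noise_sd = 0.05, seed = 15)
  fit <- fit_pairing_model(samples, f = 0.87)
  # slope SE ~ noise/sqrt(n); accept 4 sigma
  expect_lt(abs(fit$M - 0.12), 4 * 0.12 * 0.05 / sqrt(25))
  sc <- simulate_paired_sc(20000, dual_alpha_fraction = 0.13, seed = 16)
  f_hat <- single_alpha_fraction(sc)
  expect_lt(abs(f_hat - 0.87), 4 * sqrt(0.87 * 0.13 / 20000))
})

test_that("model constructor validates its domain", {
  expect_error(pairing_model(-0.1, 0.9), "non-negative")
  expect_error(pairing_model(0.1, 0), "0, 1")
  expect_error(pairing_model(0.1, 1.2), "0, 1")
  m <- pairing_model(0.2, 0.9, lineage = "CD4")
  expect_s3_class(m, "pairing_model")
  expect_output(print(m), "0.2")
})
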