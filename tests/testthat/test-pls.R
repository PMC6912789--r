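test_that("model specification is validated", {
  expect_error(pls_spec(list(A = "x", B = "x"),
                        data.frame(from = "A", to = "B")), "exactly one")
  expect_error(pls_spec(list(A = "x", B = "y"),
                        data.frame(from = "A", to = "C")), "declared latents")
  expect_error(pls_spec(list(A = "x", B = "y"),
                        data.frame(from = c("A", "B"), to = c("B", "A"))),
               "cycle")
  sp <- default_pls_spec("gilt")
  expect_true("betweenness_IR" %in% sp$blocks$C_IR)
  expect_false("betweenness_IR" %in% default_pls_spec("piglet")$blocks$C_IR)
})

test_that("single-indicator blocks collapse to correlation and its square", {
  set.seed(20)
  n <- 60
  x <- rnorm(n); y <- 0.7 * x + rnorm(n, sd = 0.5)
  d <- data.frame(x = x, y = y)
  sp <- pls_spec(blocks = list(A = "x", B = "y"),
                 paths = data.frame(from = "A", to = "B"))
  fit <- fit_pls(d, sp)
  expect_true(fit$converged)
  expect_equal(unname(coef(fit)), cor(x, y), tolerance = 1e-9)
  expect_equal(unname(fit$r2["B"]), cor(x, y)^2, tolerance = 1e-9)
  expect_equal(unname(apply(fit$scores, 2, sd)), c(1, 1), tolerance = 1e-12)
})

test_that("a duplicated indicator loads perfectly and saturates AVE", {
  set.seed(21)
  x <- rnorm(50); z <- rnorm(50)
  d <- data.frame(x1 = x, x2 = x, z = z + 0.5 * x)
  sp <- pls_spec(blocks = list(A = c("x1", "x2"), B = "z"),
                 paths = data.frame(from = "A", to = "B"))
  fit <- fit_pls(d, sp)
  expect_equal(unname(fit$loadings$A), c(1, 1), tolerance = 1e-9)
  expect_equal(fit$block_quality$ave[fit$block_quality$latent == "A"], 1,
               tolerance = 1e-9)
})

test_that("latent scores return with unit variance and complete cases only", {
  d <- simulate_latent_data(120, seed = 22)
  d$d1[1:7] <- NA
  fit <- fit_pls(d, latent_spec())
  expect_equal(fit$n_dropped, 7)
  expect_equal(fit$n_used, 113)
  expect_equal(unname(apply(fit$scores, 2, sd)), rep(1, 3), tolerance = 1e-12)
  expect_error(fit_pls(transform(d, x1 = 1), latent_spec()), "constant")
  expect_error(fit_pls(d[1:5, ], latent_spec()), "fewer than 10")
})

test_that("structural paths are recovered with small bias", {
  est <- t(sapply(1:12, function(s) {
    d <- simulate_latent_data(500, g1 = 0.6, g2 = 0.3, seed = s)
    fit <- fit_pls(d, latent_spec())
    expect_true(fit$converged)
    coef(fit)
  }))
  expect_lt(abs(mean(est[, 1]) - 0.6), 0.05)
  expect_lt(abs(mean(est[, 2]) - 0.3), 0.05)
})

test_that("collinear exogenous latents can push a path beyond 1, unclamped", {
  set.seed(23)
  n <- 400
  c1 <- rnorm(n)
  c2 <- 0.95 * c1 + sqrt(1 - 0.95^2) * rnorm(n)
  d <- 1.8 * c1 - 1.0 * c2 + rnorm(n, sd = 0.3)
  ind <- function(l) l + rnorm(n, sd = 0.2)
  dat <- data.frame(d1 = ind(d), d2 = ind(d), x1 = ind(c1), x2 = ind(c1),
                    y1 = ind(c2), y2 = ind(c2))
  fit <- fit_pls(dat, latent_spec())
  expect_gt(max(abs(coef(fit))), 1)
  expect_equal(sum(sign(coef(fit))), 0)  # one positive, one negative path
})

test_that("bootstrap is reproducible and finds strong paths significant", {
  d <- simulate_latent_data(200, g1 = 0.6, g2 = 0.3, seed = 24)
  b1 <- bootstrap_paths(d, latent_spec(), n_boot = 500, seed = 7)
  b2 <- bootstrap_paths(d, latent_spec(), n_boot = 500, seed = 7)
  expect_identical(b1$replicates, b2$replicates)
  expect_true(all(b1$paths$p_value < 0.05))
  expect_true(all(b1$paths$se > 0))
  expect_equal(b1$n_boot_ok + b1$n_boot_failed, 500)
  expect_error(bootstrap_paths(d, latent_spec(), n_boot = 100), "at least 500")
})

test_that("quality gates apply the reporting thresholds", {
  d <- simulate_latent_data(300, loading = 0.9, seed = 25)
  fit <- fit_pls(d, latent_spec())
  q <- quality_gates(fit)
  ave_rows <- q$gates[q$gates$criterion == "ave_above_0.5", ]
  expect_true(all(ave_rows$pass == (ave_rows$value > 0.5)))
  cr_rows <- q$gates[q$gates$criterion == "composite_reliability_0.6_0.9", ]
  expect_true(all(cr_rows$pass == (cr_rows$value >= 0.6 & cr_rows$value <= 0.9)))
  expect_true(q$r2_band["D"] %in%
              c("negligible", "weak", "moderate", "substantial"))
  # band thresholds
  fake <- fit; fake$r2["D"] <- 0.61
  expect_equal(unname(quality_gates(fake)$r2_band["D"]), "moderate")
  fake$r2["D"] <- 0.80
  expect_equal(unname(quality_gates(fake)$r2_band["D"]), "substantial")
  fake$r2["D"] <- 0.10
  expect_equal(unname(quality_gates(fake)$r2_band["D"]), "negligible")
})

test_that("print, summary, coef and plot methods run on a fit", {
  d <- simulate_latent_data(100, seed = 26)
  fit <- fit_pls(d, latent_spec())
  expect_output(print(fit), "Structural paths")
  expect_output(print(summary(fit)), "Quality gates")
  expect_named(coef(fit), c("C1->D", "C2->D"))
  f <- withr::local_tempfile(fileext = ".png")
  grDevices::png(f); plot(fit); grDevices::dev.off()
  expect_true(file.exists(f))
})
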