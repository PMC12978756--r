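test_that("helicity vanishes for uniform flow and solid-body rotation", {
  n <- 12
  con <- gridded_field(array(1.3, c(n, n, n)), array(-0.7, c(n, n, n)),
                       array(0.2, c(n, n, n)), spacing = 0.1)
  expect_lt(max(abs(helicity_field(con))), 1e-12)
  rot <- rotation_field(n = 16, omega0 = 2.5)
  expect_lt(max(abs(helicity_field(rot))), 1e-12)
})

test_that("helicity of a linear velocity field is exact (constant vorticity)", {
  n <- 9; h <- 0.05
  x <- (seq_len(n) - 1) * h
  X <- array(x, c(n, n, n))
  Y <- array(rep(x, each = n), c(n, n, n))
  Z <- array(rep(x, each = n * n), c(n, n, n))
  # u = (2y + z, 3x - z, x + 4y): curl = (4 + 1, 1 - 1, 3 - 2) = (5, 0, 1)
  f <- gridded_field(2 * Y + Z, 3 * X - Z, X + 4 * Y, spacing = h)
  H <- helicity_field(f)
  H_exact <- (2 * Y + Z) * 5 + (X + 4 * Y) * 1
  expect_lt(max(abs(H - H_exact)), 1e-10)
})

test_that("ABC helicity equals squared speed at second order in h", {
  f16 <- abc_field(16); f32 <- abc_field(32)
  e16 <- max(abs(helicity_field(f16) - (f16$u^2 + f16$v^2 + f16$w^2)))
  e32 <- max(abs(helicity_field(f32) - (f32$u^2 + f32$v^2 + f32$w^2)))
  expect_lt(e16, 0.2)
  expect_gt(e16 / e32, 3)    # O(h^2): halving h quarters the error
  # at the origin u = (1, 1, 1): H = 3 up to discretization
  expect_equal(helicity_field(f32)[1, 1, 1], 3, tolerance = 0.02)
})

test_that("helicity scales quadratically and is reflection-invariant", {
  f <- abc_field(16, A = 0.8, B = 1.1, C = 0.5)
  H <- helicity_field(f)
  f3 <- gridded_field(3 * f$u, 3 * f$v, 3 * f$w, spacing = f$spacing,
                      periodic = TRUE)
  expect_equal(helicity_field(f3), 9 * H, tolerance = 1e-12)
  fneg <- gridded_field(-f$u, -f$v, -f$w, spacing = f$spacing, periodic = TRUE)
  expect_equal(helicity_field(fneg), H, tolerance = 1e-12)
})

test_that("ABC field is discretely divergence-free and zero at zero amplitude", {
  f <- abc_field(16)
  n <- f$dim[1]; h <- f$spacing[1]
  # independent periodic central differences along each axis
  shift <- function(a, k, axis) {
    idx <- rep(list(quote(expr = )), 3)
    idx[[axis]] <- ((seq_len(n) - 1 + k) %% n) + 1
    do.call(`[`, c(list(a), idx))
  }
  div <- (shift(f$u, 1, 1) - shift(f$u, -1, 1)) / (2 * h) +
    (shift(f$v, 1, 2) - shift(f$v, -1, 2)) / (2 * h) +
    (shift(f$w, 1, 3) - shift(f$w, -1, 3)) / (2 * h)
  expect_lt(max(abs(div)), 1e-13)
  f0 <- abc_field(8, A = 0, B = 0, C = 0)
  expect_true(all(f0$u == 0 & f0$v == 0 & f0$w == 0))
  expect_true(all(helicity_field(f0) == 0))
  expect_error(abc_field(4), class = "pulsarch_invalid_input")
})

test_that("summaries report exact min/mean/max and reject empty input", {
  s <- summarize_metric(c(1, 2, 3), "wss")
  expect_equal(unlist(s[c("min", "avg", "max")], use.names = FALSE), c(1, 2, 3))
  s2 <- summarize_metric(rep(4.2, 17))
  expect_true(s2$min == 4.2 && s2$avg == 4.2 && s2$max == 4.2)
  set.seed(99)
  x <- stats::runif(1e4)
  s3 <- summarize_metric(x)
  # independent streaming computation
  lo <- Inf; hi <- -Inf; acc <- 0
  for (v in x) { lo <- min(lo, v); hi <- max(hi, v); acc <- acc + v }
  expect_identical(s3$min, lo)
  expect_identical(s3$max, hi)
  expect_equal(s3$avg, acc / length(x), tolerance = 1e-12)
  expect_true(s3$min <= s3$avg && s3$avg <= s3$max)
  expect_error(summarize_metric(double()), class = "pulsarch_invalid_input")
  expect_error(summarize_metric(c(1, NA)), class = "pulsarch_invalid_input")
})

test_that("WSS classifier reproduces the reported exemplar colours", {
  bands <- severity_bands("wss")
  rep1 <- classify_severity(
    tibble::tibble(quantity = "wss_Pa", min = 0.005, avg = 0.041, max = 0.8),
    bands)
  expect_equal(rep1$category[rep1$metric == "avg"], "yellow")  # 0.041 Pa
  expect_equal(rep1$category[rep1$metric == "min"], "yellow")  # 0.005 Pa
  rep2 <- classify_severity(
    tibble::tibble(quantity = "wss_Pa", min = 0.2, avg = 1.1, max = 6.01),
    bands)
  expect_equal(rep2$category[rep2$metric == "max"], "red")     # 6.01 Pa
  expect_equal(rep2$category[rep2$metric == "avg"], "green")   # inside 0.4-1.5
})

test_that("band edges fall to the lower-severity side and max-severity is monotone", {
  bands <- severity_bands("wss")
  at <- function(m, v) {
    df <- tibble::tibble(quantity = "wss_Pa", min = 0.2, avg = 1.0, max = 2.0)
    df[[m]] <- v
    out <- classify_severity(df, bands)
    out$category[out$metric == m]
  }
  expect_equal(at("avg", 0.4), "green")
  expect_equal(at("avg", 1.5), "green")
  expect_equal(at("max", 1.5), "green")
  expect_equal(at("max", 4.5), "yellow")
  expect_equal(at("min", 0.05), "green")
  # monotonicity of the max metric
  lv <- sapply(seq(0.1, 8, by = 0.1), function(v) severity_level(at("max", v)))
  expect_true(all(diff(lv) >= 0))
})

test_that("classifier rejects malformed summaries and bands", {
  bands <- severity_bands("wss")
  expect_error(classify_severity(tibble::tibble(a = 1), bands),
               class = "pulsarch_invalid_input")
  badband <- list(min = list(breaks = c(2, 1), categories = c("a", "b", "c")),
                  avg = bands$avg, max = bands$max)
  expect_error(
    classify_severity(tibble::tibble(min = 1, avg = 1, max = 1), badband),
    class = "pulsarch_invalid_input")
})
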