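test_that("rho hits the monotone boundaries", {
  x <- c(3, 7, 11, 20, 41)
  expect_equal(spearman_test(x, exp(x))$rho, 1)
  expect_equal(spearman_test(x, -x^3)$rho, -1)
})

test_that("exact rho and permutation P match cor.test enumeration at n = 5", {
  set.seed(19)
  for (i in 1:20) {
    x <- sample(100, 5); y <- sample(100, 5)   # no ties
    mine <- spearman_test(x, y)
    ref <- stats::cor.test(x, y, method = "spearman", exact = TRUE)
    expect_identical(mine$method, "exact")
    expect_equal(mine$rho, unname(ref$estimate))
    expect_equal(mine$p, ref$p.value, tolerance = 1e-12)
  }
})

test_that("asymptotic P agrees with the t-approximation reference", {
  set.seed(23)
  x <- rnorm(40); y <- x + rnorm(40, 0, 2)
  mine <- spearman_test(x, y)
  expect_identical(mine$method, "asymptotic")
  ref <- stats::cor.test(x, y, method = "spearman", exact = FALSE)
  expect_equal(mine$rho, unname(ref$estimate))
  expect_equal(mine$p, ref$p.value, tolerance = 1e-6)
})

test_that("rho is invariant under strictly monotone transforms", {
  set.seed(29)
  x <- rlnorm(12); y <- rnorm(12)
  base <- spearman_test(x, y)$rho
  expect_equal(spearman_test(log(x), y)$rho, base)
  expect_equal(spearman_test(x, exp(y / 2))$rho, base)
  expect_equal(spearman_test(rank(x), y)$rho, base)
})

test_that("ties are handled with average ranks", {
  x <- c(1, 2, 2, 3, 5, 5, 5, 9)
  y <- c(2, 1, 4, 4, 6, 7, 7, 10)
  expect_equal(spearman_test(x, y)$rho,
               stats::cor(rank(x), rank(y)))
})

test_that("degenerate correlation inputs are rejected", {
  expect_error(spearman_test(1:3, 1:3), "n >= 4")
  expect_error(spearman_test(rep(1, 6), 1:6), "constant")
  expect_error(spearman_test(1:4, 1:5), "paired")
})

test_that("the network keeps only significant edges with signed attributes", {
  set.seed(37)
  n <- 24
  driver <- rep(c(1, 0.5), each = n / 2) * rlnorm(n, 0, 0.1)
  params <- data.frame(I0 = driver * 100, CPS = driver * 10 * rlnorm(n, 0, 0.05))
  endpoints <- data.frame(
    good = driver * rlnorm(n, 0, 0.05),          # positively tied
    bad = (2 - driver) * rlnorm(n, 0, 0.05),     # negatively tied
    noise = rnorm(n))                            # unrelated
  net <- spearman_network(params, endpoints, threshold = 0.05)
  expect_true(all(net$edges$p <= 0.05))
  expect_true(all(abs(net$edges$rho) <= 1))
  expect_identical(net$edges$sign, sign(net$edges$rho))
  pick <- function(s, t) net$edges[net$edges$source == s & net$edges$target == t, ]
  expect_identical(pick("I0", "good")$sign, 1)
  expect_identical(pick("I0", "bad")$sign, -1)
  expect_identical(pick("CPS", "good")$sign, 1)
  # node roster covers both sides
  expect_setequal(net$nodes$name[net$nodes$type == "parameter"], c("I0", "CPS"))
})

test_that("constant endpoints are skipped with a warning", {
  params <- data.frame(I0 = rnorm(10))
  endpoints <- data.frame(flat = rep(2, 10), ok = rnorm(10))
  expect_warning(net <- spearman_network(params, endpoints), "skipping pair")
  expect_false("flat" %in% net$all_pairs$target)
})

test_that("network exports round-trip as edge-list CSV and GraphML", {
  set.seed(41)
  x <- rnorm(20)
  net <- spearman_network(data.frame(p1 = x),
                          data.frame(e1 = x + rnorm(20, 0, 0.2)))
  csv <- tempfile(fileext = ".csv")
  write_network_csv(net, csv)
  back <- utils::read.csv(csv)
  expect_identical(names(back), c("source", "target", "rho", "p", "sign"))
  expect_equal(back$rho, net$edges$rho, tolerance = 1e-12)
  gml <- tempfile(fileext = ".graphml")
  write_network_graphml(net, gml)
  g <- igraph::read_graph(gml, format = "graphml")
  expect_equal(igraph::gsize(g), nrow(net$edges))
  unlink(c(csv, gml))
})

test_that("quality classification applies the indirubin standard", {
  tab <- data.frame(group = c("control", "salt_low", "salt_high", "drought"),
                    indirubin = c(0.1, 0.095, 0.018, 0.046))
  q <- classify_quality(tab)
  expect_identical(q$pass, c(TRUE, TRUE, FALSE, TRUE))
  # boundary content passes (>= rule) and zeros all fail
  expect_true(classify_quality(data.frame(group = "g", indirubin = 0.02))$pass)
  expect_false(any(classify_quality(
    data.frame(group = c("a", "b"), indirubin = c(0, 0)))$pass))
  expect_error(classify_quality(data.frame(group = "g", indigo = 1)),
               "indirubin")
  expect_error(classify_quality(data.frame(group = "g", indirubin = -1)),
               ">= 0")
})
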