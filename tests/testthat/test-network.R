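test_that("the default spec encodes the published layer schedule", {
  sp <- network_spec()
  expect_equal(sp$input_size, 120)
  expect_equal(sp$base_channels, 16)
  # channel plan: 16 along the up path, 32 after each concat fusion
  expect_equal(sp$out_channels, c(rep(16L, 6), rep(32L, 4)))
  net <- build_network(sp, seed = 1)
  # first block maps RGB to 16 channels with 3x3 kernels
  expect_equal(dim(net$params$W1), c(9 * 3, 16))
  # concat fusions see 16+16 and 32+16 input channels
  expect_equal(dim(net$params$W7), c(9 * 32, 32))
  expect_equal(dim(net$params$W9), c(9 * 48, 32))
  expect_equal(length(net$params$Wh), 32)
  # the parameter count of the default spec is fixed
  n <- sum(vapply(net$params, length, integer(1)))
  expect_equal(n, 53905)
})

test_that("building twice with one seed yields identical parameters", {
  a <- build_network(network_spec(), seed = 42)
  b <- build_network(network_spec(), seed = 42)
  expect_identical(a$params, b$params)
  c <- build_network(network_spec(), seed = 43)
  expect_false(identical(a$params, c$params))
})

test_that("forward output matches the input spatial size, single channel", {
  net <- build_network(network_spec(input_size = 20, base_channels = 4),
                       seed = 2)
  x <- array(runif(20 * 20 * 3), dim = c(20, 20, 3))
  out <- net_forward(net, x)
  expect_equal(dim(out), c(20, 20))
  expect_true(all(out >= 0))  # rectified output
  # deterministic in evaluation mode, and permutation maps through lists
  expect_identical(net_forward(net, x), out)
  xs <- lapply(1:3, function(i) array(runif(20 * 20 * 3), dim = c(20, 20, 3)))
  outs <- net_forward(net, xs)
  expect_identical(net_forward(net, rev(xs)), rev(outs))
  expect_error(net_forward(net, array(0, dim = c(20, 20, 2))), "channels")
})

test_that("a zeroed prediction head yields an all-zero map", {
  net <- build_network(network_spec(input_size = 16, base_channels = 2),
                       seed = 3)
  net$params$Wh <- net$params$Wh * 0
  net$params$bh <- 0
  x <- array(runif(16 * 16 * 3), dim = c(16, 16, 3))
  expect_true(all(net_forward(net, x) == 0))
})

test_that("evaluation forward agrees with the double-precision reference", {
  net <- build_network(network_spec(input_size = 12, base_channels = 2),
                       seed = 5)
  set.seed(6)
  x <- array(runif(12 * 12 * 3), dim = c(12, 12, 3))
  ref <- ref_net_forward_eval(net$params, net$running, x)
  got <- net_forward(net, x)
  expect_equal(got, ref, tolerance = 1e-5)
})

test_that("binarize follows the literal thresholding rule", {
  m <- matrix(c(-0.2, 0, 0.3, 1.5), 2, 2)
  expect_identical(as.vector(binarize(m, 0)), c(0L, 0L, 1L, 1L))
  expect_true(all(binarize(matrix(-1, 3, 3)) == 0))
  b <- binarize(m, 0.5)
  expect_identical(binarize(b, 0.5), b)  # idempotent
  expect_identical(binarize(b, 0), b)
  expect_error(binarize(matrix(NaN, 2, 2)), "NA")
})

test_that("a trained state is not trivially flip-symmetric", {
  # forward on a tile and on its horizontal flip should differ once the
  # kernels are generic (a symmetry here would indicate degenerate weights)
  net <- build_network(network_spec(input_size = 16, base_channels = 2),
                       seed = 8)
  x <- array(runif(16 * 16 * 3), dim = c(16, 16, 3))
  xf <- x[, 16:1, , drop = FALSE]
  out <- net_forward(net, x)
  outf <- net_forward(net, xf)[, 16:1]
  expect_false(isTRUE(all.equal(out, outf)))
})
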