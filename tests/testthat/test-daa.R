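test_that("the Gaussian kernel follows the printed form", {
  expect_equal(gaussian_kernel(c(1, 2, 3), c(1, 2, 3), 5), 1)
  x <- c(0, 0, 0)
  y <- c(3, 0, 0)
  expect_equal(gaussian_kernel(x, y, 3), exp(-1))
  set.seed(1)
  for (i in 1:5) {
    a <- rnorm(3); b <- rnorm(3)
    expect_equal(gaussian_kernel(a, b, 1.7), gaussian_kernel(b, a, 1.7))
  }
})

test_that("control-point grids have the analytic node counts", {
  box <- mesh3t(as.matrix(expand.grid(c(0, 100), c(0, 100), c(0, 100))),
                rbind(c(1, 2, 3), c(2, 4, 3), c(1, 3, 5)))
  g <- init_control_points(box, 50, pad = 0)
  expect_equal(nrow(g), 27)
  g2 <- init_control_points(box, 1000, pad = 0)
  expect_equal(nrow(g2), 8)
  # default padding of sigma/2 per side
  g3 <- init_control_points(box, 50)
  expect_equal(nrow(g3), (ceiling(150 / 50) + 1)^3)
})

test_that("the velocity field is a linear superposition of kernels", {
  q <- rbind(c(0, 0, 0))
  mu <- rbind(c(1, 0, 0))
  expect_equal(velocity_field(rbind(c(0, 0, 0)), q, mu, 2),
               rbind(c(1, 0, 0)))
  expect_equal(velocity_field(rbind(c(2, 0, 0)), q, mu, 2),
               rbind(c(exp(-1), 0, 0)))
  q2 <- rbind(c(0, 0, 0), c(5, 1, -2))
  mu2 <- rbind(c(1, 0, 0), c(0, -2, 1))
  x <- matrix(rnorm(9), 3)
  v_sum <- velocity_field(x, q2[1, , drop = FALSE], mu2[1, , drop = FALSE], 2) +
    velocity_field(x, q2[2, , drop = FALSE], mu2[2, , drop = FALSE], 2)
  expect_equal(velocity_field(x, q2, mu2, 2), v_sum)
})

test_that("geodesic shooting has its closed-form behaviours", {
  # zero momenta: fixed point
  q0 <- matrix(rnorm(9), 3)
  tr0 <- geodesic_shoot(q0, matrix(0, 3, 3), 2, n_steps = 4)
  expect_equal(tr0$q[[5]], q0)
  expect_equal(tr0$mu[[5]], matrix(0, 3, 3))
  # single control point: exact translation for any step count
  for (ns in c(1, 3, 10)) {
    q1 <- rbind(c(1, -2, 0.5))
    m1 <- rbind(c(0.3, 2, -1))
    tr <- geodesic_shoot(q1, m1, 5, n_steps = ns)
    expect_lt(max(abs(tr$q[[ns + 1]] - (q1 + m1))), 1e-10)
    expect_lt(max(abs(tr$mu[[ns + 1]] - m1)), 1e-10)
  }
  expect_error(geodesic_shoot(q0, matrix(NaN, 3, 3), 2))
})

test_that("total momentum is conserved and matches a fine-step reference", {
  set.seed(31)
  q0 <- matrix(rnorm(6), 2)
  mu0 <- matrix(rnorm(6), 2)
  tr <- geodesic_shoot(q0, mu0, 1.5, n_steps = 20)
  expect_lt(max(abs(colSums(tr$mu[[21]]) - colSums(mu0))), 1e-6)
  fine <- geodesic_shoot(q0, mu0, 1.5, n_steps = 200)
  expect_lt(max(abs(tr$q[[21]] - fine$q[[201]])), 1e-3)
})

test_that("Hamiltonian drift stays below 1e-3 on random 5-point systems", {
  for (s in 1:5) {
    set.seed(s)
    q0 <- matrix(rnorm(15), 5)
    mu0 <- matrix(rnorm(15, sd = 0.7), 5)
    tr <- geodesic_shoot(q0, mu0, 1.5, n_steps = 20)
    H0 <- hamiltonian(q0, mu0, 1.5)
    H1 <- hamiltonian(tr$q[[21]], tr$mu[[21]], 1.5)
    expect_lt(abs(H1 - H0) / abs(H0), 1e-3)
  }
})

test_that("mesh flow rides the deformation exactly where it should", {
  m <- generate_base_mesh(2, 1)
  q <- rbind(c(10, 0, 0))
  # zero momenta: unchanged
  tr0 <- geodesic_shoot(q, rbind(c(0, 0, 0)), 3)
  expect_equal(flow_mesh(m, tr0)$vertices, m$vertices)
  # a vertex coincident with the single control point translates with it
  m2 <- mesh3t(rbind(c(10, 0, 0), c(1000, 0, 0), c(1000, 1, 0)),
               rbind(c(1, 2, 3)))
  mu <- rbind(c(1, 2, -0.5))
  tr <- geodesic_shoot(q, mu, 3, n_steps = 20)
  out <- flow_mesh(m2, tr)
  expect_lt(max(abs(out$vertices[1, ] - (q + mu))), 1e-6)
  # vertices far beyond the kernel reach barely move
  expect_lt(max(abs(out$vertices[2, ] - m2$vertices[2, ])),
            exp(-100) * sqrt(sum(mu^2)) * 10)
})

test_that("attachment distances match the brute-force double-sum oracle", {
  for (s in 1:4) {
    a <- random_patch_mesh(s, n_extra = s)
    b <- random_patch_mesh(s + 50, n_extra = 5 - s)
    for (mode in c("current", "varifold")) {
      impl <- mesh_attachment_distance(a, b, 1.3, mode)
      orac <- oracle_attachment(a, b, 1.3, mode == "varifold")
      expect_lt(abs(impl - orac), 1e-12)
      expect_equal(mesh_attachment_distance(b, a, 1.3, mode), impl,
                   tolerance = 1e-12)
      expect_gte(impl, 0)
    }
  }
  a <- random_patch_mesh(3)
  for (mode in c("current", "varifold"))
    expect_lt(mesh_attachment_distance(a, a, 0.8, mode), 1e-9)
})

test_that("varifold mode skips zero-area faces instead of dividing by zero", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(0, 1, 0))
  degen <- mesh3t(v, rbind(c(1, 2, 3), c(1, 2, 4)))  # first face is flat
  b <- random_patch_mesh(9)
  d <- mesh_attachment_distance(degen, b, 1, "varifold")
  expect_true(is.finite(d))
})

test_that("atlas loss scales as documented with the noise parameter", {
  m <- generate_base_mesh(1, 0)
  spec_meshes <- list(generate_base_mesh(1.1, 0), generate_base_mesh(0.9, 0))
  q <- init_control_points(m, 1)
  set.seed(33)
  mus <- list(matrix(rnorm(nrow(q) * 3, sd = 0.05), nrow(q)),
              matrix(rnorm(nrow(q) * 3, sd = 0.05), nrow(q)))
  mk <- function(noise) daa_atlas(m, q, mus, list(sigma = 1, sigma_w = 0.5),
                                  noise_sigma = noise, n_steps = 3)
  l1 <- atlas_loss(mk(1), spec_meshes)
  l2 <- atlas_loss(mk(2), spec_meshes)
  expect_equal(l2$data_terms, l1$data_terms / 4, tolerance = 1e-10)
  expect_equal(l2$regularity_terms, l1$regularity_terms, tolerance = 1e-12)
  # zero momenta: regularity vanishes, data term positive for mismatched
  # template
  mus0 <- lapply(mus, function(x) x * 0)
  l0 <- atlas_loss(daa_atlas(m, q, mus0, list(sigma = 1, sigma_w = 0.5),
                             n_steps = 3), spec_meshes)
  expect_equal(l0$regularity_terms, c(0, 0))
  expect_true(all(l0$data_terms > 0))
  # identical template and specimens at zero momenta: total loss 0
  same <- atlas_loss(daa_atlas(m, q, mus0[1], list(sigma = 1, sigma_w = 0.5),
                               n_steps = 3), list(m))
  expect_lt(same$total, 1e-12)
})

test_that("analytic gradients agree with central finite differences", {
  set.seed(7)
  tmpl <- generate_base_mesh(1, 0)  # 12 vertices
  q <- matrix(runif(12, -1, 1), 4)  # 4 control points
  mus <- list(matrix(rnorm(12, sd = 0.3), 4), matrix(rnorm(12, sd = 0.3), 4))
  specimens <- list(generate_base_mesh(1.2, 0), generate_base_mesh(0.9, 0))
  for (mode in c("varifold", "current")) {
    model <- daa_atlas(tmpl, q, mus, list(sigma = 1, sigma_w = 0.5),
                       noise_sigma = 0.7, attachment = mode, n_steps = 5)
    g <- atlas_gradient(model, specimens)
    h <- 1e-5
    lossf <- function(m) atlas_loss(m, specimens)$total
    check_block <- function(get, set, gmat) {
      v <- get(model)
      fd <- vapply(seq_along(v), function(i) {
        vp <- v; vp[i] <- vp[i] + h
        vm <- v; vm[i] <- vm[i] - h
        (lossf(set(model, vp)) - lossf(set(model, vm))) / (2 * h)
      }, 0)
      max(abs(fd - as.vector(gmat)) / pmax(abs(fd), 1e-6))
    }
    expect_lt(check_block(function(m) m$template$vertices,
                          function(m, v) {
                            m$template$vertices <- matrix(v, ncol = 3); m
                          }, g$grad_template), 1e-4)
    expect_lt(check_block(function(m) m$control_points,
                          function(m, v) {
                            m$control_points <- matrix(v, ncol = 3); m
                          }, g$grad_control_points), 1e-4)
    expect_lt(check_block(function(m) m$momenta[[1]],
                          function(m, v) {
                            m$momenta[[1]] <- matrix(v, ncol = 3); m
                          }, g$grad_momenta[[1]]), 1e-4)
  }
})

test_that("atlas estimation is a no-op on an already-perfect population", {
  tmpl <- generate_base_mesh(10, 1)
  specimens <- list(tmpl, tmpl, tmpl)
  fit <- estimate_atlas(specimens, tmpl, kernel = list(sigma = 8),
                        max_iter = 10, n_steps = 3)
  expect_lt(max(abs(do.call(rbind, fit$momenta))), 1e-6)
  expect_lt(max(abs(fit$template$vertices - tmpl$vertices)), 1e-6)
})

test_that("accepted-step losses are monotone non-increasing", {
  set.seed(35)
  base <- generate_base_mesh(10, 1)
  q <- init_control_points(base, 8)
  mus <- lapply(1:3, function(i) matrix(rnorm(nrow(q) * 3, sd = 0.6),
                                        nrow(q)))
  scheme <- synthetic_landmark_scheme(base, n_fixed = 10, n_curves = 2,
                                      curve_length = 4)
  specimens <- lapply(mus, function(m)
    synthesize_specimen(base, q, m, 8, scheme)$mesh)
  fit <- estimate_atlas(specimens, base, kernel = list(sigma = 8),
                        max_iter = 8, n_steps = 3)
  expect_true(all(diff(fit$loss_trace) <= 0))
  expect_lt(fit$loss_trace[length(fit$loss_trace)], fit$loss_trace[1])
})
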