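test_that("the base mesh is a projected icosphere with forced topology", {
  ico <- generate_base_mesh(1, 0)
  expect_equal(nrow(ico$vertices), 12)
  expect_equal(nrow(ico$faces), 20)
  expect_equal(euler_characteristic(ico), 2)
  m <- generate_base_mesh(50, 3)
  expect_true(is_watertight(m))
  expect_lt(max(abs(sqrt(rowSums(m$vertices^2)) - 50)), 1e-9 * 50)
  # outward orientation: normals point away from the origin
  ofs <- oriented_face_set(m)
  expect_true(all(rowSums(ofs$centres * ofs$normals) > 0))
  expect_error(generate_base_mesh(-1, 0))
})

test_that("pure-birth phylogenies are ultrametric, binary and reproducible", {
  tr <- generate_phylogeny(16, seed = 1)
  depths <- ape::node.depth.edgelength(tr)[1:16]
  expect_lt(diff(range(depths)), 1e-9)
  expect_equal(tr$Nnode, 15)
  expect_true(all(tr$edge.length > 0))
  expect_identical(ape::write.tree(tr),
                   ape::write.tree(generate_phylogeny(16, seed = 1)))
  tr2 <- generate_phylogeny(2, seed = 3)
  expect_equal(tr2$Nnode, 1)
  d2 <- ape::node.depth.edgelength(tr2)[1:2]
  expect_lt(abs(d2[1] - d2[2]), 1e-9)
  expect_error(generate_phylogeny(1))
})

test_that("population momenta follow the stated generative decomposition", {
  base <- generate_base_mesh(40, 1)
  q <- init_control_points(base, 25)
  # all variance parameters zero -> exactly zero momenta
  sp0 <- population_spec(n_specimens = 4, subdivision_level = 1,
                         elongation_sd = 0, bm_rate = 0,
                         individual_noise_sd = 0, seed = 2)
  tr <- generate_phylogeny(4, 2)
  sim0 <- simulate_population_momenta(sp0, tr, q)
  expect_true(all(vapply(sim0$momenta, function(m) all(m == 0), TRUE)))
  # determinism: bitwise-identical on repeat
  sp <- population_spec(n_specimens = 4, subdivision_level = 1, seed = 5)
  tr5 <- generate_phylogeny(4, 5)
  expect_identical(simulate_population_momenta(sp, tr5, q),
                   simulate_population_momenta(sp, tr5, q))
})

test_that("Brownian tip-contrast variance matches the closed form", {
  # 2-tip tree with depth t: Var(tip1 - tip2) = 2 * rate * t per coordinate
  base <- generate_base_mesh(40, 0)
  q <- init_control_points(base, 40)
  tr <- generate_phylogeny(2, seed = 1)  # unit depth
  rate <- 2.5
  contrasts <- matrix(0, 2000, 6)
  for (r in seq_len(2000)) {
    sp <- population_spec(n_specimens = 2, elongation_sd = 0,
                          bm_rate = rate, individual_noise_sd = 0,
                          seed = r)
    sim <- simulate_population_momenta(sp, tr, q)
    d <- sim$momenta[[1]] - sim$momenta[[2]]
    contrasts[r, ] <- as.vector(d)[1:6]
  }
  v <- mean(apply(contrasts, 2, var))
  expect_lt(abs(v - 2 * rate * 1) / (2 * rate), 0.1)
})

test_that("specimen synthesis is the identity at zero momenta and tracks landmarks", {
  base <- generate_base_mesh(40, 2)
  q <- init_control_points(base, 25)
  scheme <- synthetic_landmark_scheme(base)
  out0 <- synthesize_specimen(base, q, matrix(0, nrow(q), 3), 25, scheme)
  expect_equal(out0$mesh$vertices, base$vertices)
  expect_lt(max(abs(out0$landmarks$points -
                      base$vertices[scheme$vertex_indices, ])), 1e-12)
  # tracked landmarks equal the deformed vertices exactly
  mu <- 0.1 * stretch_pattern(q)
  out <- synthesize_specimen(base, q, mu, 25, scheme)
  expect_lt(max(abs(out$landmarks$points -
                      out$mesh$vertices[scheme$vertex_indices, ])), 1e-12)
  # positive stretch strictly extends the x-extent
  expect_gt(diff(range(out$mesh$vertices[, 1])),
            diff(range(base$vertices[, 1])))
  expect_error(synthesize_specimen(base, q, mu[-1, ], 25, scheme))
})

test_that("the modality artifact removes a cap and opens the surface", {
  m <- generate_base_mesh(20, 2)
  open_m <- introduce_modality_artifact(m, 1, 8)
  expect_lt(nrow(open_m$faces), nrow(m$faces))
  expect_false(is_watertight(open_m))
  expect_true(euler_characteristic(open_m) != 2)
  # a radius too small to catch any centroid leaves the mesh unchanged
  expect_identical(introduce_modality_artifact(m, 1, 1e-6), m)
  expect_error(introduce_modality_artifact(m, 1, 1e4))
})

test_that("build_study writes deterministic files and honours the floor rule", {
  sp <- population_spec(n_specimens = 10, subdivision_level = 1,
                        open_fraction = 0.5, seed = 7)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  st1 <- build_study(sp, d1)
  st2 <- build_study(sp, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)), info = f)
  }
  expect_equal(sum(st1$modality_labels == "open"), 5)
  expect_equal(length(st1$meshes), 10)
  expect_setequal(st1$tree$tip.label, names(st1$meshes))
  expect_true(all(table(st1$group_labels) >= 1))
  # open specimens are open, closed are watertight
  wt <- vapply(st1$meshes, is_watertight, TRUE)
  expect_equal(unname(wt), st1$modality_labels == "closed")
})

test_that("with open_fraction zero every mesh is watertight", {
  sp <- population_spec(n_specimens = 6, subdivision_level = 1,
                        open_fraction = 0, seed = 3)
  st <- build_study(sp)
  expect_true(all(vapply(st$meshes, is_watertight, TRUE)))
  # landmark schemes are identical across specimens
  npts <- vapply(st$landmarks, function(l) nrow(l$points), 1L)
  expect_true(all(npts == npts[1]))
})
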