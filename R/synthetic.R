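#' Specification of a synthetic study population
#'
#' Bundles the generative parameters of a seeded synthetic mesh population:
#' cranium-scale closed surfaces deformed from a common base shape by
#' geodesic shooting, with a dominant elongation axis (the dolichocephalic-
#' brachycephalic analogue), clade-structured Brownian-motion variation on a
#' pure-birth phylogeny, iid individual noise, an optional open-surface
#' modality artifact, and ecological group labels.
#'
#' @param n_specimens Number of specimens (>= 2; default 20).
#' @param base_radius Base sphere radius, mm (default 40: an 80 mm object).
#' @param subdivision_level Icosphere subdivision level (default 3).
#' @param kernel_width_true True deformation kernel width, mm (default 25).
#' @param elongation_sd SD of the dimensionless elongation coefficient
#'   (default 0.15, i.e. roughly 15 percent length changes).
#' @param bm_rate Brownian-motion rate per momentum coordinate per unit
#'   branch length, mm^2 (default 1; the tree has unit depth).
#' @param individual_noise_sd SD of iid per-coordinate momentum noise, mm
#'   (default 0.5).
#' @param open_fraction Proportion of specimens given the open-surface
#'   artifact (default 0).
#' @param cap_radius_factor Radius of the removed surface cap as a fraction
#'   of `base_radius` (default 1), applied at a fixed "ventral" location so
#'   the artifact is anatomically consistent across open specimens, as it
#'   is in real CT populations.
#' @param internal_radius_factor Radius of the internal structure carried
#'   by open specimens as a fraction of `base_radius` (default 0.7).  CT-
#'   derived meshes contain internal surfaces that surface scans lack;
#'   watertight closing solidifies them away, which is what removes the
#'   modality artifact.
#' @param n_groups Number of ecological groups (default 2, assigned by the
#'   clades splitting at the root).
#' @param seed Integer seed; every stochastic component draws from a named
#'   sub-stream of it.
#' @return Object of class `population_spec` (a validated list).
#' @export
population_spec <- function(n_specimens = 20L, base_radius = 40,
                            subdivision_level = 3L, kernel_width_true = 25,
                            elongation_sd = 0.15, bm_rate = 1,
                            individual_noise_sd = 0.5, open_fraction = 0,
                            cap_radius_factor = 1,
                            internal_radius_factor = 0.7,
                            n_groups = 2L, seed = 1L) {
  stopifnot(n_specimens >= 2L, base_radius > 0,
            open_fraction >= 0, open_fraction <= 1,
            elongation_sd >= 0, bm_rate >= 0, individual_noise_sd >= 0,
            cap_radius_factor > 0, internal_radius_factor > 0,
            internal_radius_factor < 1)
  structure(list(n_specimens = as.integer(n_specimens),
                 base_radius = base_radius,
                 subdivision_level = as.integer(subdivision_level),
                 kernel_width_true = kernel_width_true,
                 elongation_sd = elongation_sd, bm_rate = bm_rate,
                 individual_noise_sd = individual_noise_sd,
                 open_fraction = open_fraction,
                 cap_radius_factor = cap_radius_factor,
                 internal_radius_factor = internal_radius_factor,
                 n_groups = as.integer(n_groups), seed = as.integer(seed)),
            class = "population_spec")
}

# one global seed feeds a named sub-stream per component
substream_seed <- function(seed, component) {
  offsets <- c(tree = 11L, momenta = 23L, modality = 37L, groups = 41L,
               jitter = 53L)
  (seed * 101L + offsets[[component]]) %% .Machine$integer.max
}

#' Generate the base mesh: a subdivided icosahedron
#'
#' Subdivides an icosahedron `level` times (each triangle into four) and
#' projects every vertex onto the sphere of the given radius: a closed,
#' consistently outward-oriented genus-0 surface with `20 * 4^level` faces.
#'
#' @param radius Sphere radius, mm (> 0).
#' @param subdivision_level Number of subdivision rounds (>= 0).
#' @return A watertight [mesh3t()] centred at the origin.
#' @export
generate_base_mesh <- function(radius, subdivision_level = 0L) {
  if (radius <= 0) stop("radius must be positive")
  if (subdivision_level < 0) stop("subdivision_level must be >= 0")
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, phi, 0), c(1, phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
             c(0, -1, phi), c(0, 1, phi), c(0, -1, -phi), c(0, 1, -phi),
             c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(subdivision_level)) {
    nf <- nrow(f)
    edge_id <- new.env(hash = TRUE)
    vlist <- v
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      id <- edge_id[[key]]
      if (is.null(id)) {
        vlist <<- rbind(vlist, (vlist[a, ] + vlist[b, ]) / 2)
        id <- nrow(vlist)
        edge_id[[key]] <- id
      }
      id
    }
    newf <- matrix(0L, 4 * nf, 3)
    for (i in seq_len(nf)) {
      a <- f[i, 1]; b <- f[i, 2]; c_ <- f[i, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, c_); ca <- midpoint(c_, a)
      newf[4 * i - 3, ] <- c(a, ab, ca)
      newf[4 * i - 2, ] <- c(b, bc, ab)
      newf[4 * i - 1, ] <- c(c_, ca, bc)
      newf[4 * i, ] <- c(ab, bc, ca)
    }
    v <- vlist
    f <- newf
  }
  v <- v * (radius / sqrt(rowSums(v^2)))
  mesh3t(v, f, specimen_id = "base")
}

#' Simulate a rooted ultrametric phylogeny
#'
#' Pure-birth (Yule) sampling via [ape::rphylo()], rescaled to unit
#' root-to-tip depth, with tips labelled `spec_001 ...`.  The same seed
#' yields the identical Newick string.
#'
#' @param n_tips Number of tips (>= 2).
#' @param seed Integer seed.
#' @return An [ape::ape-package] `phylo` object (rooted, binary,
#'   ultrametric, positive branch lengths).
#' @export
generate_phylogeny <- function(n_tips, seed = 1L) {
  if (n_tips < 2L) stop("n_tips must be >= 2")
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(substream_seed(seed, "tree"))
  tree <- ape::rphylo(n_tips, birth = 1, death = 0)
  depth <- max(ape::node.depth.edgelength(tree))
  tree$edge.length <- tree$edge.length / depth
  tree$tip.label <- sprintf("spec_%03d", seq_len(n_tips))
  tree
}

#' Momentum pattern that elongates the shape along one axis
#'
#' Momenta proportional to each control point's signed coordinate along the
#' stretch axis: the induced velocity field stretches the object smoothly
#' along that axis, mimicking the dominant elongation axis of cranial
#' variation.
#'
#' @param control_points `p x 3` matrix.
#' @param axis 1, 2 or 3 (default 1 = x).
#' @return `p x 3` momenta matrix (mm).
#' @export
stretch_pattern <- function(control_points, axis = 1L) {
  m <- matrix(0, nrow(control_points), 3)
  m[, axis] <- control_points[, axis]
  m
}

#' Simulate per-specimen momenta with known structure
#'
#' `mu_i = alpha_i * M_stretch + BM_i + eps_i`: a shared elongation pattern
#' scaled by `alpha_i ~ N(0, elongation_sd^2)`, a Brownian-motion component
#' evolved on the phylogeny with rate `bm_rate` per coordinate, and iid
#' `N(0, individual_noise_sd^2)` noise per momentum coordinate.  Seeded and
#' reproducible through the spec's `momenta` sub-stream.
#'
#' @param spec A [population_spec()].
#' @param tree Phylogeny whose tips index the specimens.
#' @param control_points `p x 3` matrix (the true control grid).
#' @return List with `momenta` (list of `p x 3`, in tip-label order
#'   spec_001...), `elongation` (the alpha vector) and `stretch` (the
#'   pattern used).
#' @export
simulate_population_momenta <- function(spec, tree, control_points) {
  n <- spec$n_specimens
  if (length(tree$tip.label) != n)
    stop("tree tip count must equal n_specimens")
  p <- nrow(control_points)
  Ms <- stretch_pattern(control_points)
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(substream_seed(spec$seed, "momenta"))
  alpha <- stats::rnorm(n, 0, spec$elongation_sd)
  C <- ape::vcv(tree)
  ord <- order(rownames(C))  # tip-label order spec_001..., row i = specimen i
  C <- C[ord, ord]
  L <- t(chol(C + diag(1e-12, n)))
  bm <- L %*% matrix(stats::rnorm(n * 3 * p, 0, sqrt(spec$bm_rate)), n)
  noise <- matrix(stats::rnorm(n * 3 * p, 0, spec$individual_noise_sd), n)
  momenta <- lapply(seq_len(n), function(i) {
    alpha[i] * Ms + matrix(bm[i, ] + noise[i, ], p, 3, byrow = TRUE)
  })
  names(momenta) <- sprintf("spec_%03d", seq_len(n))
  list(momenta = momenta, elongation = alpha, stretch = Ms)
}

#' Synthesise one specimen by geodesic shooting
#'
#' Flows the base mesh under the geodesic generated by the given momenta and
#' tracks a fixed subset of base vertex indices as the specimen's landmark
#' configuration, so landmark homology is exact by construction.
#'
#' @param base The base [mesh3t()].
#' @param control_points `p x 3` matrix.
#' @param momenta `p x 3` matrix for this specimen.
#' @param kernel_width_true Kernel width, mm.
#' @param landmark_scheme A list from [synthetic_landmark_scheme()]:
#'   `vertex_indices` plus `curves`.
#' @param n_steps,integrator Shooting discretisation.
#' @return List with `mesh` and `landmarks` (a [landmark_config()]).
#' @export
synthesize_specimen <- function(base, control_points, momenta,
                                kernel_width_true, landmark_scheme,
                                n_steps = 10L, integrator = "rk2") {
  if (any(!is.finite(momenta))) stop("non-finite momenta")
  if (nrow(momenta) != nrow(control_points))
    stop("momenta shape must match control point count")
  traj <- geodesic_shoot(control_points, momenta, kernel_width_true,
                         n_steps, integrator)
  mesh <- flow_mesh(base, traj)
  lm <- landmark_config(mesh$vertices[landmark_scheme$vertex_indices, ,
                                      drop = FALSE],
                        curves = landmark_scheme$curves,
                        specimen_id = mesh$specimen_id)
  list(mesh = mesh, landmarks = lm)
}

#' Deterministic landmark scheme on the base sphere
#'
#' Picks `n_fixed` well-spread base vertices (furthest-point sampling from
#' vertex 1) as fixed landmarks plus `n_curves` meridian-like curves of
#' `curve_length` points each (nearest base vertices to equally spaced
#' latitudes at fixed longitudes), a scale model of a fixed + curve-
#' semilandmark cranial scheme.
#'
#' @param base The base [mesh3t()].
#' @param n_fixed Number of fixed landmarks (default 30).
#' @param n_curves Number of curves (default 4).
#' @param curve_length Points per curve (default 6).
#' @return List with `vertex_indices` (into the base vertices) and `curves`
#'   (index vectors into the landmark configuration).
#' @export
synthetic_landmark_scheme <- function(base, n_fixed = 30L, n_curves = 4L,
                                      curve_length = 6L) {
  v <- base$vertices
  nv <- nrow(v)
  # furthest-point sampling for the fixed landmarks
  sel <- 1L
  d <- sqrt(rowSums(sweep(v, 2, v[1L, ])^2))
  while (length(sel) < n_fixed) {
    cand <- which.max(d)
    sel <- c(sel, cand)
    d <- pmin(d, sqrt(rowSums(sweep(v, 2, v[cand, ])^2)))
  }
  # curve targets: fixed-longitude meridian arcs
  r <- sqrt(mean(rowSums(v^2)))
  curve_vidx <- list()
  taken <- sel
  for (ci in seq_len(n_curves)) {
    lon <- 2 * pi * (ci - 1) / n_curves + pi / 7
    lat <- seq(-pi / 3, pi / 3, length.out = curve_length)
    target <- cbind(r * cos(lat) * cos(lon), r * cos(lat) * sin(lon),
                    r * sin(lat))
    idx <- integer(curve_length)
    for (k in seq_len(curve_length)) {
      dd <- rowSums(sweep(v, 2, target[k, ])^2)
      dd[taken] <- Inf
      idx[k] <- which.min(dd)
      taken <- c(taken, idx[k])
    }
    curve_vidx[[ci]] <- idx
  }
  vertex_indices <- c(sel, unlist(curve_vidx))
  curves <- list()
  pos <- n_fixed
  for (ci in seq_len(n_curves)) {
    curves[[ci]] <- pos + seq_len(curve_length)
    pos <- pos + curve_length
  }
  list(vertex_indices = vertex_indices, curves = curves)
}

#' Remove a cap of faces to emulate an open CT-derived surface
#'
#' Deletes every face whose centroid lies within `cap_radius` (Euclidean) of
#' the given vertex, leaving a boundary: the open-surface modality artifact
#' of mixed mesh populations.
#'
#' @param mesh A closed [mesh3t()].
#' @param cap_center_vertex Index of the vertex at the cap centre.
#' @param cap_radius Cap radius, mm (> 0).
#' @return An open [mesh3t()] (unchanged when no centroid qualifies).
#' @export
introduce_modality_artifact <- function(mesh, cap_center_vertex, cap_radius) {
  if (cap_radius <= 0) stop("cap_radius must be positive")
  ctr <- mesh$vertices[cap_center_vertex, ]
  cen <- suppressWarnings(oriented_face_set(mesh))$centres
  drop_ <- sqrt(rowSums(sweep(cen, 2, ctr)^2)) < cap_radius
  if (all(drop_)) stop("cap would remove every face")
  if (!any(drop_)) return(mesh)
  mesh3t(mesh$vertices, mesh$faces[!drop_, , drop = FALSE],
         specimen_id = mesh$specimen_id)
}

#' Build a complete synthetic study
#'
#' Orchestrates the generators: base mesh, phylogeny, momenta, one mesh +
#' landmark configuration per specimen, modality labels (`floor(
#' open_fraction * n)` specimens chosen by a seeded draw), and group labels
#' from the clades splitting at the root.  "Open"-modality specimens
#' emulate CT-derived meshes: they carry an internal structure (a concentric
#' shell at `internal_radius_factor * base_radius`, deformed by the same
#' specimen flow) and lose a ventral surface cap of radius
#' `cap_radius_factor * base_radius` at a fixed anatomical location, so the
#' artifact is consistent across open specimens; "closed" specimens are the
#' outer surface only, emulating surface scans.  Watertight closing
#' solidifies the internal structure away and fills the cap, which is what
#' removes the modality artifact downstream.  Optionally writes
#' `specimen_###.ply`, `landmarks_###.csv`, `tree.nwk` and `metadata.csv`
#' (byte-identical across runs at the same seed).
#'
#' @param spec A [population_spec()].
#' @param out_dir Output directory, or `NULL` (default) for in-memory only.
#' @return Object of class `synthetic_study`: meshes, landmarks,
#'   true momenta, elongation coefficients, modality and group labels, tree,
#'   control points and the spec.
#' @export
build_study <- function(spec, out_dir = NULL) {
  n <- spec$n_specimens
  base <- generate_base_mesh(spec$base_radius, spec$subdivision_level)
  tree <- generate_phylogeny(n, spec$seed)
  q <- init_control_points(base, spec$kernel_width_true)
  sim <- simulate_population_momenta(spec, tree, q)
  scheme <- synthetic_landmark_scheme(base)
  ids <- sprintf("spec_%03d", seq_len(n))
  meshes <- vector("list", n)
  landmarks <- vector("list", n)
  for (i in seq_len(n)) {
    b <- base
    b$specimen_id <- ids[i]
    out <- synthesize_specimen(b, q, sim$momenta[[i]],
                               spec$kernel_width_true, scheme)
    meshes[[i]] <- out$mesh
    landmarks[[i]] <- out$landmarks
  }
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed",
                                                      globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(substream_seed(spec$seed, "modality"))
  n_open <- floor(spec$open_fraction * n)
  open_idx <- sort(sample.int(n, n_open))
  modality <- ifelse(seq_len(n) %in% open_idx, "open", "closed")
  if (n_open > 0) {
    inner <- generate_base_mesh(spec$internal_radius_factor *
                                  spec$base_radius, spec$subdivision_level)
    combined <- mesh3t(rbind(base$vertices, inner$vertices),
                       rbind(base$faces,
                             inner$faces + nrow(base$vertices)))
    cap_v <- which.min(base$vertices[, 3])  # fixed ventral location
    for (i in open_idx) {
      out <- synthesize_specimen(combined, q, sim$momenta[[i]],
                                 spec$kernel_width_true, scheme)
      m <- out$mesh
      m$specimen_id <- ids[i]
      meshes[[i]] <- introduce_modality_artifact(
        m, cap_v, cap_radius = spec$cap_radius_factor * spec$base_radius)
    }
  }
  groups <- clade_groups(tree, spec$n_groups)
  names(meshes) <- names(landmarks) <- ids
  study <- structure(list(meshes = meshes, landmarks = landmarks,
                          true_momenta = sim$momenta,
                          elongation = sim$elongation,
                          modality_labels = modality,
                          group_labels = groups[ids], tree = tree,
                          control_points = q, landmark_scheme = scheme,
                          base = base, spec = spec),
                     class = "synthetic_study")
  if (!is.null(out_dir)) write_study(study, out_dir)
  study
}

# group labels from the clades splitting at the root (n_groups = 2) or by
# cutting the tree into balanced clades
clade_groups <- function(tree, n_groups = 2L) {
  n <- length(tree$tip.label)
  root <- n + 1L
  kids <- tree$edge[tree$edge[, 1] == root, 2]
  grp <- setNames(rep("g1", n), tree$tip.label)
  if (n_groups >= 2L) {
    right <- if (kids[2] <= n) tree$tip.label[kids[2]] else
      ape::extract.clade(tree, kids[2])$tip.label
    grp[right] <- "g2"
  }
  if (n_groups > 2L) {
    # further split the larger clades at their own roots
    for (g in seq(3L, n_groups)) {
      tab <- table(grp)
      big <- names(tab)[which.max(tab)]
      members <- names(grp)[grp == big]
      mrca <- ape::getMRCA(tree, members)
      sub <- tree$edge[tree$edge[, 1] == mrca, 2][1]
      inner <- if (sub <= n) tree$tip.label[sub] else
        ape::extract.clade(tree, sub)$tip.label
      grp[intersect(members, inner)] <- paste0("g", g)
    }
  }
  grp
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(paste0("<synthetic_study> %d specimens (radius %g mm, level ",
                     "%d), %d control points, %d open\n"),
              x$spec$n_specimens, x$spec$base_radius,
              x$spec$subdivision_level, nrow(x$control_points),
              sum(x$modality_labels == "open")))
  invisible(x)
}

write_study <- function(study, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ids <- names(study$meshes)
  for (i in seq_along(ids)) {
    write_ply(study$meshes[[i]],
              file.path(out_dir, sprintf("specimen_%03d.ply", i)))
    lm <- study$landmarks[[i]]$points
    df <- data.frame(landmark_id = seq_len(nrow(lm)),
                     x = sprintf("%.10g", lm[, 1]),
                     y = sprintf("%.10g", lm[, 2]),
                     z = sprintf("%.10g", lm[, 3]))
    utils::write.csv(df, file.path(out_dir, sprintf("landmarks_%03d.csv", i)),
                     row.names = FALSE, quote = FALSE)
  }
  ape::write.tree(study$tree, file.path(out_dir, "tree.nwk"))
  meta <- data.frame(specimen_id = ids, modality = study$modality_labels,
                     group = unname(study$group_labels),
                     elongation_coefficient = sprintf("%.10g",
                                                      study$elongation))
  utils::write.csv(meta, file.path(out_dir, "metadata.csv"),
                   row.names = FALSE, quote = FALSE)
  invisible(out_dir)
}
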