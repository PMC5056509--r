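test_that("contact areas follow the closed-form sphere overlap", {
  # two carbon atoms 20 A apart: far beyond contact range
  far <- point_structure(rbind(c(0, 0, 0), c(20, 0, 0)))
  expect_equal(contact_map(far)$areas[1, 2], 0)

  # equal probe-expanded spheres (R = 1.7 + 1.4) at d = 3.1: the
  # intersection circle has radius^2 = R^2 - (d/2)^2
  d <- 3.1
  near <- point_structure(rbind(c(0, 0, 0), c(d, 0, 0)))
  R <- 1.7 + 1.4
  oracle <- pi * (R^2 - (d / 2)^2)
  expect_equal(contact_map(near)$areas[1, 2], oracle, tolerance = 1e-12)

  # symmetry, non-negativity and zero diagonal on a random fixture
  s <- small_strand(c("LEU", "ASP", "VAL", "LYS", "PHE"))
  cm <- contact_map(s)$areas
  expect_identical(cm, t(cm))
  expect_true(all(cm >= 0))
  expect_true(all(diag(cm) == 0))

  # rigid motion invariance
  rz <- matrix(c(0, -1, 0, 1, 0, 0, 0, 0, 1), 3, 3, byrow = TRUE)
  s2 <- s
  s2$xyz <- s$xyz %*% t(rz) + matrix(c(4, -7, 2), nrow(s$xyz), 3, byrow = TRUE)
  expect_equal(contact_map(s2)$areas, cm, tolerance = 1e-9)
})

test_that("trajectory-averaged maps equal the mean of per-frame maps", {
  toy <- make_toy_structure(n_strands_per_sheet = 1, strand_length = 5,
                            seed = 61)
  static <- make_toy_trajectory(toy, n_frames = 3, sigma = 0, seed = 1)
  single <- contact_map(frame_structure(static, 1))
  avg <- mean_contact_map(static)
  expect_equal(avg$areas, single$areas)
  expect_equal(avg$n_frames_averaged, 3)

  traj <- make_toy_trajectory(toy, n_frames = 4, sigma = 0.3, seed = 2)
  sub <- c(2, 4)
  direct <- Reduce(`+`, lapply(sub, function(i) {
    contact_map(frame_structure(traj, i))$areas
  })) / length(sub)
  expect_equal(mean_contact_map(traj, frame_ids = sub)$areas, direct)
  expect_error(mean_contact_map(traj, frame_ids = integer(0)), "empty")
})

test_that("difference maps are signed, antisymmetric in their arguments", {
  mk <- function(m, label) vhhscreen:::new_contact_map(m, label = label)
  a <- matrix(c(0, 2, 1, 0,
                2, 0, 3, 0,
                1, 3, 0, 5,
                0, 0, 5, 0), 4, 4)
  b <- matrix(c(0, 1, 4, 0,
                1, 0, 0, 2,
                4, 0, 0, 5,
                0, 2, 5, 0), 4, 4)
  d <- difference_contact_map(mk(a, "var"), mk(b, "ref"))
  expect_equal(d$areas, a - b)
  d_rev <- difference_contact_map(mk(b, "ref"), mk(a, "var"))
  expect_equal(d_rev$areas, -d$areas)
  expect_equal(difference_contact_map(mk(a, "x"), mk(a, "x"))$areas,
               matrix(0, 4, 4))
  expect_error(difference_contact_map(mk(a, "x"),
                                      mk(matrix(0, 5, 5), "y")),
               "same number of residues")
})

test_that("the per-residue global difference excludes sequence neighbours", {
  mkd <- function(m) {
    out <- vhhscreen:::new_contact_map(m, type = "difference")
    out
  }
  expect_equal(global_difference(mkd(matrix(0, 4, 4)))$values, rep(0, 4))

  # entries only between sequence-adjacent residues vanish entirely
  adj <- matrix(0, 5, 5)
  for (i in 1:4) adj[i, i + 1] <- adj[i + 1, i] <- 7
  expect_equal(global_difference(mkd(adj))$values, rep(0, 5))

  # hand-computed 5x5 example: entries (1,3) = -2 and (1,5) = 3
  m <- matrix(0, 5, 5)
  m[1, 3] <- m[3, 1] <- -2
  m[1, 5] <- m[5, 1] <- 3
  expect_equal(global_difference(mkd(m))$values, c(5, 0, 2, 0, 3))
  # strict one-sided reading: each entry counts once, toward the lower index
  expect_equal(global_difference(mkd(m), one_sided = TRUE)$values,
               c(5, 0, 0, 0, 0))
})

test_that("perturbed-residue selection applies the 20%-above-mean rule", {
  mkp <- function(v) {
    structure(list(values = v, variant_label = "v", reference_label = "r"),
              class = "perturbation_profile")
  }
  # threshold 1.2 * mean(c(1,1,1,10)) = 3.9: only the peak passes
  expect_equal(select_perturbed_residues(mkp(c(1, 1, 1, 10))), 4)
  expect_length(select_perturbed_residues(mkp(rep(2, 6))), 0)
  expect_length(select_perturbed_residues(mkp(rep(0, 6))), 0)
  # values below the absolute floor are never flagged
  expect_length(select_perturbed_residues(mkp(c(0.01, 0.01, 0.5, 0.01))), 0)
  expect_equal(select_perturbed_residues(mkp(c(0.01, 0.01, 0.5, 0.01)),
                                         min_value = 0.1), 3)
})

test_that("SASA matches closed forms and is rigid-motion invariant", {
  iso <- point_structure(matrix(c(0, 0, 0), 1, 3))
  a_iso <- sasa(iso)$atom[1]
  expect_equal(a_iso, 4 * pi * 3.1^2, tolerance = 0.01)

  # two far-apart atoms: no occlusion, areas add
  two <- point_structure(rbind(c(0, 0, 0), c(30, 0, 0)))
  expect_equal(sum(sasa(two)$atom), 2 * a_iso, tolerance = 1e-9)

  # an atom enclosed in a cage of neighbours is fully buried
  cage_pts <- vhhscreen:::golden_spiral_points(40) * 2.8
  cage <- point_structure(rbind(c(0, 0, 0), cage_pts),
                          atom_names = c("CA", sprintf("C%02d", 1:40)),
                          resnames = c("ALA", rep("GLY", 40)))
  expect_lt(sasa(cage)$atom[1], 1)

  s <- small_strand()
  tot <- sum(sasa(s)$residue)
  rz <- matrix(c(0, 0, 1, 1, 0, 0, 0, 1, 0), 3, 3, byrow = TRUE)
  s2 <- s
  s2$xyz <- s$xyz %*% rz + matrix(c(-3, 9, 1), nrow(s$xyz), 3, byrow = TRUE)
  # the deterministic point set is fixed in the lab frame, so invariance
  # holds to sampling accuracy
  expect_equal(sum(sasa(s2)$residue), tot, tolerance = 0.01)
  # per-atom SASA never exceeds the isolated-sphere bound
  expect_true(all(sasa(s)$atom <= 4 * pi * (1.8 + 1.4)^2 + 1e-9))
})

test_that("the hydrophobic-exposure gate needs both exposure and stickiness", {
  leu <- build_peptide("LEU")
  expect_identical(hydrophobic_exposed_residues(leu, n_points = 480), 1L)
  asp <- build_peptide("ASP")
  expect_length(hydrophobic_exposed_residues(asp, n_points = 480), 0)

  # a LEU buried inside a cage of carbon atoms fails the exposure gate
  leu_atoms <- leu$atoms[leu$atoms$res_index == 1, ]
  cage_pts <- sweep(vhhscreen:::golden_spiral_points(60) * 6, 2,
                    colMeans(leu$xyz), `+`)
  atoms <- rbind(leu_atoms,
                 data.frame(type = "ATOM", eleno = 6:65,
                            elety = sprintf("C%02d", 1:60), resid = "GLY",
                            chain = "A", resno = 2, insert = "", elesy = "C",
                            res_index = 2))
  buried <- vhhscreen:::new_structure(atoms, rbind(leu$xyz, cage_pts),
                                      label = "buried")
  expect_false(1 %in% hydrophobic_exposed_residues(buried, n_points = 480))

  # unknown residue types are excluded with a warning
  odd <- point_structure(rbind(c(0, 0, 0), c(30, 0, 0)),
                         resnames = c("XXX", "LEU"))
  expect_warning(sel <- hydrophobic_exposed_residues(odd, n_points = 480),
                 "XXX")
  expect_false(1 %in% sel)
})

test_that("hotspot grouping equals brute-force connected components", {
  toy <- make_toy_structure(seed = 71)
  s <- toy$structure

  # candidates far apart on opposite sheets stay singleton patches
  iso <- group_hotspots(c(1, 24), s, link_distance = 6)
  expect_length(iso$patches, 2)
  expect_true(all(lengths(iso$patches) == 1))

  # a chain of consecutive candidates merges into one patch
  chain <- group_hotspots(1:6, s, link_distance = 8)
  expect_length(chain$patches, 1)
  expect_equal(chain$patches[[1]], 1:6)

  set.seed(61)
  for (trial in 1:8) {
    cand <- sort(sample(1:24, sample(4:10, 1)))
    link <- runif(1, 3, 9)
    got <- group_hotspots(cand, s, link_distance = link, max_patches = 24)
    want <- brute_force_patches(s, cand, link)
    sizes <- vapply(want, length, integer(1))
    want <- want[order(-sizes, vapply(want, min, numeric(1)))]
    expect_equal(got$patches, want)
  }
  expect_error(group_hotspots(integer(0), s), "no candidate")
})

test_that("patch retention and monotonicity in the linking distance hold", {
  strand <- build_peptide(rep(c("LEU", "SER", "ASN", "THR"), 7)) # 28 residues
  cand <- seq(1, 28, by = 4) # 7 candidates, 15.2 A apart
  hs <- group_hotspots(cand, strand, link_distance = 8)
  expect_length(hs$patches, 5) # only the five largest are retained
  expect_equal(unlist(hs$patches), c(1, 5, 9, 13, 17)) # ties by min index

  n_patches <- vapply(c(4, 8, 16, 24), function(link) {
    length(group_hotspots(cand, strand, link_distance = link,
                          max_patches = 28)$patches)
  }, integer(1))
  expect_true(all(diff(n_patches) <= 0))
})

test_that("the rearrangement report ranks residues by contact change", {
  toy <- make_toy_structure(seed = 81)
  pair <- make_mutant_pair(toy, perturbed_residues = 8, amplitude = 3,
                           seed = 9, n_frames = 20)
  ref_map <- mean_contact_map(pair$reference)
  var_map <- mean_contact_map(pair$variant)
  d <- difference_contact_map(var_map, ref_map)
  hotspot <- c(2, 8, 20)
  rep_var <- frame_structure(pair$variant, 1)
  rep_ref <- frame_structure(pair$reference, 1)
  rpt <- hotspot_rearrangement_report(hotspot, d, rep_var, rep_ref,
                                      n_points = 240)
  expect_equal(nrow(rpt), length(hotspot))
  expect_setequal(rpt$res_index, hotspot)
  expect_true(all(diff(abs(rpt$delta_contact)) <= 1e-12))
  # the displaced residue dominates the bystander far from the mutation
  expect_gt(rpt$delta_contact[rpt$res_index == 8],
            rpt$delta_contact[rpt$res_index == 20])

  # identical structures: all changes vanish
  zero <- difference_contact_map(ref_map, ref_map)
  rpt0 <- hotspot_rearrangement_report(hotspot, zero, rep_ref, rep_ref,
                                       n_points = 240)
  expect_true(all(rpt0$delta_contact == 0))
  expect_true(all(rpt0$delta_sasa == 0))
  small <- frame_structure(make_toy_trajectory(
    make_toy_structure(n_strands_per_sheet = 1, strand_length = 3, seed = 1),
    n_frames = 1, sigma = 0, seed = 1), 1)
  expect_error(hotspot_rearrangement_report(1, zero, small, rep_ref),
               "same number of residues")
})
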