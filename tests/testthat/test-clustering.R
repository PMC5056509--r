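test_that("fluctuating-residue gating follows the above-mean rule", {
  # uniform profile: nothing is strictly above the mean
  expect_error(select_fluctuating_residues(rep(1, 8), 0), "manually")
  expect_equal(select_fluctuating_residues(c(0.5, 0.5, 2.0, 0.5, 0.5), 0), 3)
  # a peak sitting on an excluded terminus is dropped
  prof <- c(3, 0.5, 0.5, 2, 0.5, 0.5, 0.5, 0.5)
  expect_equal(select_fluctuating_residues(prof, 0), c(1, 4))
  expect_equal(select_fluctuating_residues(prof, 1), 4)
  expect_error(select_fluctuating_residues(c(1, 2), 1), "whole chain")
})

test_that("RMSD matrices are symmetric and match frame-pairwise calls", {
  toy <- make_toy_structure(seed = 41)
  static <- make_toy_trajectory(toy, n_frames = 3, sigma = 0, seed = 1)
  expect_lt(max(rmsd_matrix(static)$values), 1e-8)

  traj <- make_toy_trajectory(toy, n_frames = 4, sigma = 0.4, seed = 2)
  idx <- select_atoms(traj$topology, "backbone")
  m <- rmsd_matrix(traj, idx)
  expect_identical(m$values, t(m$values))
  expect_true(all(diag(m$values) == 0))
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(m$values[i, j],
                 rmsd(traj$frames[[i]], traj$frames[[j]], idx, fit = TRUE))
  }
  # relabeling frames permutes rows and columns consistently
  perm <- c(3, 1, 4, 2)
  traj_p <- manual_trajectory(traj$topology, traj$frames[perm])
  m_p <- rmsd_matrix(traj_p, idx)
  expect_equal(m_p$values, m$values[perm, perm])
})

test_that("gromos clustering follows the greedy rule and the size gate", {
  # all pairs beyond the cutoff: every frame its own cluster
  m_far <- structure(list(values = random_rmsd_like_matrix(6, 3) + 5,
                          frame_ids = 1:6), class = "rmsd_matrix")
  diag(m_far$values) <- 0
  res <- gromos_cluster(m_far, cutoff = 1, min_size = 1)
  expect_length(res$clusters, 6)
  expect_true(all(vapply(res$clusters, function(cl) length(cl$members),
                         integer(1)) == 1))

  # two well-separated 5-frame bundles
  m <- matrix(5, 10, 10)
  m[1:5, 1:5] <- 0.5
  m[6:10, 6:10] <- 0.5
  diag(m) <- 0
  rm10 <- structure(list(values = m, frame_ids = 1:10), class = "rmsd_matrix")
  res2 <- gromos_cluster(rm10, cutoff = 1, min_size = 2)
  expect_length(res2$clusters, 2)
  expect_equal(sort(vapply(res2$clusters, function(cl) length(cl$members),
                           integer(1))), c(5, 5))
  expect_equal(res2$clusters[[1]]$members, 1:5) # size tie: lower centre first

  # the automatic cutoff is the mean of the strict upper triangle
  set.seed(77)
  mv <- random_rmsd_like_matrix(7)
  rm7 <- structure(list(values = mv, frame_ids = 1:7), class = "rmsd_matrix")
  res3 <- gromos_cluster(rm7, cutoff = "auto", min_size = 1)
  expect_equal(res3$cutoff_used, mean(mv[upper.tri(mv)]))

  # min_size gate moves small clusters to discarded and errors when empty
  expect_error(gromos_cluster(m_far, cutoff = 1, min_size = 3),
               "below min_size")
})

test_that("cluster sizes and discarded frames always partition the ensemble", {
  set.seed(88)
  for (trial in 1:50) {
    n <- sample(4:10, 1)
    mv <- random_rmsd_like_matrix(n)
    rm <- structure(list(values = mv, frame_ids = seq_len(n)),
                    class = "rmsd_matrix")
    res <- gromos_cluster(rm, cutoff = runif(1, 0.5, 2.5), min_size = 1)
    members <- unlist(lapply(res$clusters, `[[`, "members"))
    expect_setequal(c(members, res$discarded), seq_len(n))
    expect_equal(length(members) + length(res$discarded), n)
    for (cl in res$clusters) expect_true(cl$center %in% cl$members)
  }
})

test_that("gromos clustering matches the brute-force transcription", {
  set.seed(99)
  for (trial in 1:200) {
    n <- sample(3:10, 1)
    mv <- random_rmsd_like_matrix(n)
    rm <- structure(list(values = mv, frame_ids = seq_len(n)),
                    class = "rmsd_matrix")
    cutoff <- runif(1, 0.3, 2.5)
    got <- gromos_cluster(rm, cutoff = cutoff, min_size = 1)
    want <- brute_force_gromos(mv, cutoff)
    sizes <- vapply(want, function(cl) length(cl$members), integer(1))
    centers <- vapply(want, function(cl) cl$center, integer(1))
    want <- want[order(-sizes, centers)]
    expect_equal(got$clusters, want)
  }
})

test_that("the representative is the centre of the most populated cluster", {
  toy <- make_toy_structure(seed = 51)
  base <- toy$structure
  alt <- base$xyz
  alt[base$atoms$res_index == 5, ] <- alt[base$atoms$res_index == 5, ] + 5
  frames <- c(replicate(8, base$xyz, simplify = FALSE),
              replicate(3, alt, simplify = FALSE))
  traj <- manual_trajectory(base, frames)
  res <- gromos_cluster(rmsd_matrix(traj), cutoff = 0.5, min_size = 1)
  expect_equal(length(res$clusters[[1]]$members), 8)
  rep_str <- representative_conformation(traj, res)
  expect_equal(rep_str$xyz, base$xyz)

  # size tie: the cluster whose centre has the lower frame index wins
  frames_tie <- c(replicate(5, base$xyz, simplify = FALSE),
                  replicate(5, alt, simplify = FALSE))
  traj_tie <- manual_trajectory(base, frames_tie)
  res_tie <- gromos_cluster(rmsd_matrix(traj_tie), cutoff = 0.5, min_size = 1)
  expect_equal(res_tie$clusters[[1]]$center, 1)
  expect_equal(representative_conformation(traj_tie, res_tie)$xyz, base$xyz)
})
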