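# hexagonal ring coordinates in the plane spanned by (v, w), centered at ctr
hexagon <- function(ctr, v = c(1, 0, 0), w = c(0, 1, 0), r = 1.39) {
  t(vapply((0:5) * pi / 3, function(a) ctr + r * (cos(a) * v + sin(a) * w),
           numeric(3)))
}

test_that("pocket definition applies the 6 A heavy-atom cutoff", {
  # ligand far from every residue
  prot <- cbind(seq(0, 27, 3), 0, 0)
  far <- matrix(c(0, 100, 0), 1)
  st <- tiny_structure(rbind(prot, far),
                       role = rep(c("protein", "ligand"), c(10, 1)),
                       resno = c(1:10, 11))
  expect_equal(define_pocket(st$xyz, st, 11), integer(0))

  # 5.9 A included, 6.1 A excluded
  two <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 5.9, 0))
  st2 <- tiny_structure(two, role = c("protein", "protein", "ligand"),
                        resno = c(1, 2, 3))
  expect_equal(define_pocket(st2$xyz, st2, 3), 1L)
  two[3, 2] <- 6.1
  st3 <- tiny_structure(two, role = c("protein", "protein", "ligand"),
                        resno = c(1, 2, 3))
  expect_equal(define_pocket(st3$xyz, st3, 3), integer(0))

  # the designed toy pocket is recovered exactly from the manifest geometry
  st4 <- generate_topology()
  lig <- select_atoms(st4, role = "ligand")
  refs <- toy_state_refs(st4)
  pocket <- define_pocket(refs$closed, st4, lig)
  dist_min <- vapply(sort(unique(st4$atoms$resno[st4$atoms$role == "protein"])),
                     function(r) {
    ra <- select_atoms(st4, role = "protein", residues = r)
    min(sqrt(rowSums((refs$closed[lig, , drop = FALSE][rep(1, 0), ] - 0))),
        min(apply(refs$closed[lig, , drop = FALSE], 1, function(p)
          min(sqrt(rowSums(sweep(refs$closed[ra, , drop = FALSE], 2, p)^2))))))
  }, numeric(1))
  expect_setequal(pocket, which(dist_min <= 6))
})

test_that("pocket membership grows monotonically with the cutoff", {
  sys <- toy_system(n_frames = 1, noise_sd = 0.1, seed = 3)
  lig <- select_atoms(sys$structure, role = "ligand")
  xyz <- sys$traj$coords[1, , ]
  prev <- integer(0)
  for (cutoff in c(4, 5, 6, 8, 12)) {
    cur <- define_pocket(xyz, sys$structure, lig, cutoff)
    expect_true(all(prev %in% cur))
    prev <- cur
  }
})

test_that("hydrogen bonds fire inside and not outside the thresholds", {
  # ligand donor N with explicit H, protein acceptor O at 2.9 A, 170 deg
  don <- c(0, 0, 0)
  h <- c(1.0, 0, 0)
  acc <- c(2.9 * cos(10 * pi / 180), 2.9 * sin(10 * pi / 180), 0)
  # D-H...A angle: vectors H->D and H->A
  xyz <- rbind(acc, don, h)
  st <- tiny_structure(xyz, elem = c("O", "N", "H"),
                       role = c("protein", "ligand", "ligand"),
                       resno = c(1, 2, 2),
                       acceptor = c(TRUE, FALSE, FALSE),
                       donor = c(FALSE, TRUE, FALSE),
                       bonds = data.frame(i = 2, j = 3, r0 = 1, k = 300))
  hits <- detect_frame_interactions(xyz, st, 2:3)
  expect_true(any(hits$type == "HBDonor" & hits$resno == 1))

  # same pair at 4.5 A: no H-bond
  xyz2 <- xyz; xyz2[1, ] <- c(4.5, 0, 0)
  st2 <- st; st2$xyz <- xyz2
  hits2 <- detect_frame_interactions(xyz2, st2, 2:3)
  expect_false(any(hits2$type == "HBDonor"))

  # bad D-H...A angle (~90 deg) blocks the bond even at short range
  xyz3 <- rbind(c(1.0, 2.0, 0), don, h)
  hits3 <- detect_frame_interactions(xyz3, st, 2:3)
  expect_false(any(hits3$type == "HBDonor"))
})

test_that("pi-stacking fires for parallel offset rings and respects tilt", {
  v <- c(1, 0, 0); w <- c(0, 1, 0)
  prot_ring <- hexagon(c(0, 0, 0), v, w)
  # parallel ring 3.8 A above, 1 A lateral offset, 5 deg tilt
  tilt <- 5 * pi / 180
  v2 <- c(cos(tilt), 0, sin(tilt))
  lig_ring <- hexagon(c(1, 0, 3.8), v2, w)
  xyz <- rbind(prot_ring, lig_ring)
  st <- tiny_structure(xyz, elem = "C",
                       role = rep(c("protein", "ligand"), each = 6),
                       resno = rep(c(1, 2), each = 6),
                       aromatic = TRUE, ring = rep(c(1L, 2L), each = 6))
  hits <- detect_frame_interactions(xyz, st, 7:12)
  expect_true(any(hits$type == "PiStacking" & hits$resno == 1))

  # centroids 7 A apart: no stacking
  far_ring <- hexagon(c(0, 0, 7), v, w)
  xyzf <- rbind(prot_ring, far_ring)
  stf <- tiny_structure(xyzf, elem = "C",
                        role = rep(c("protein", "ligand"), each = 6),
                        resno = rep(c(1, 2), each = 6),
                        aromatic = TRUE, ring = rep(c(1L, 2L), each = 6))
  expect_false(any(detect_frame_interactions(xyzf, stf, 7:12)$type ==
                   "PiStacking"))

  # 45 deg tilt at 5 A: neither face-to-face nor edge-to-face window
  v3 <- c(cos(pi / 4), 0, sin(pi / 4))
  mid_ring <- hexagon(c(0, 0, 5), v3, c(0, 1, 0))
  # rotate normal: construct ring in plane (v3, w) -> normal tilted 45 deg
  xyzm <- rbind(prot_ring, mid_ring)
  stm <- tiny_structure(xyzm, elem = "C",
                        role = rep(c("protein", "ligand"), each = 6),
                        resno = rep(c(1, 2), each = 6),
                        aromatic = TRUE, ring = rep(c(1L, 2L), each = 6))
  expect_false(any(detect_frame_interactions(xyzm, stm, 7:12)$type ==
                   "PiStacking"))
})

test_that("ionic and cation-pi types follow the ligand-perspective naming", {
  # ligand cation 3.4 A from protein anion -> Cationic
  xyz <- rbind(c(0, 0, 0), c(3.4, 0, 0))
  st <- tiny_structure(xyz, elem = c("O", "N"),
                       role = c("protein", "ligand"), resno = c(1, 2),
                       anion = c(TRUE, FALSE), cation = c(FALSE, TRUE),
                       charge = c(-1, 1))
  hits <- detect_frame_interactions(xyz, st, 2)
  expect_true(any(hits$type == "Cationic" & hits$resno == 1))
  expect_false(any(hits$type == "Anionic"))

  # protein cation over a ligand ring centroid -> CationPi
  ring <- hexagon(c(0, 0, 0))
  xyz2 <- rbind(c(0, 0, 3.5), ring)
  st2 <- tiny_structure(xyz2, elem = c("N", rep("C", 6)),
                        role = c("protein", rep("ligand", 6)),
                        resno = c(1, rep(2, 6)),
                        cation = c(TRUE, rep(FALSE, 6)),
                        aromatic = c(FALSE, rep(TRUE, 6)),
                        ring = c(NA, rep(1L, 6)))
  hits2 <- detect_frame_interactions(xyz2, st2, 2:7)
  expect_true(any(hits2$type == "CationPi" & hits2$resno == 1))

  # missing typing flags are reported by atom
  st_bad <- st
  st_bad$atoms$cation[2] <- NA
  expect_error(detect_frame_interactions(xyz, st_bad, 2), "typing")
})

test_that("frequencies count firing frames and honor the strict threshold", {
  xyz_on <- rbind(c(0, 0, 0), c(4.0, 0, 0))
  xyz_off <- rbind(c(0, 0, 0), c(40, 0, 0))
  st <- tiny_structure(xyz_on, elem = "C", role = c("protein", "ligand"),
                       resno = c(1, 2), hydrophobic = TRUE)
  tr <- traj_from_frames(list(xyz_on, xyz_off))
  ft <- interaction_frequencies(tr, st, 2)
  expect_equal(ft$raw$frequency, 50)
  tr2 <- traj_from_frames(list(xyz_on, xyz_on))
  ft2 <- interaction_frequencies(tr2, st, 2)
  expect_equal(ft2$raw$frequency, 100)
  # strictly-greater-than reporting rule
  ft3 <- interaction_frequencies(traj_from_frames(
    list(xyz_on, xyz_off, xyz_on, xyz_off, xyz_on,
         xyz_off, xyz_on, xyz_off, xyz_on, xyz_off)), st, 2,
    report_threshold = 50)
  expect_equal(ft3$raw$frequency, 50)
  expect_equal(nrow(ft3$reported), 0)
})

test_that("frequencies are invariant under frame permutation and rerun", {
  sys <- toy_system(n_frames = 60, noise_sd = 0.1, seed = 28)
  lig <- select_atoms(sys$structure, role = "ligand")
  a <- interaction_frequencies(sys$traj, sys$structure, lig)
  set.seed(1)
  perm <- sample(60)
  b <- interaction_frequencies(
    new_trajectory(sys$traj$coords[perm, , ]), sys$structure, lig)
  expect_equal(a$raw, b$raw)
  c <- interaction_frequencies(sys$traj, sys$structure, lig)
  expect_identical(a$raw, c$raw)
})

test_that("generator-designed interaction frequencies are recovered", {
  # fast-mixing chain with 80/20 occupancy keeps the sampling error well
  # inside the tolerance at 5000 frames
  hT <- matrix(c(0.8, 0.2, 0.8, 0.2), 2, byrow = TRUE)
  sys <- toy_system(n_frames = 5000, noise_sd = 0.1, seed = 101,
                    hidden_T = hT)
  expect_equal(sys$manifest$stationary, c(0.8, 0.2), tolerance = 1e-10)
  lig <- select_atoms(sys$structure, role = "ligand")
  ft <- interaction_frequencies(sys$traj, sys$structure, lig)
  des <- sys$manifest$interactions
  expect_gte(nrow(des), 4)
  for (r in seq_len(nrow(des))) {
    got <- ft$raw$frequency[ft$raw$resno == des$resno[r] &
                            ft$raw$type == des$type[r]]
    if (length(got) == 0) got <- 0
    expect_lt(abs(got - 100 * des$fraction[r]), 3)
  }
})

test_that("fingerprint comparison reports deltas over the row union", {
  a <- data.frame(resno = c(16, 68), type = "Hydrophobic",
                  frequency = c(77, 61.2))
  b <- data.frame(resno = 16, type = "Hydrophobic", frequency = 37)
  d <- compare_fingerprints(a, b)
  expect_equal(nrow(d), 2)
  expect_equal(d$delta[d$resno == 68], -61.2)
  expect_equal(d$delta[d$resno == 16], -40)
  expect_true(all(diff(abs(d$delta)) <= 0))
  # identical tables -> all zeros
  z <- compare_fingerprints(a, a)
  expect_true(all(z$delta == 0))
})

test_that("a planted mutation removes its hydrogen-bond row", {
  hT <- matrix(c(0.8, 0.2, 0.8, 0.2), 2, byrow = TRUE)
  sys <- toy_system(n_frames = 300, noise_sd = 0.1, seed = 55, hidden_T = hT)
  st <- sys$structure
  lig <- select_atoms(st, role = "ligand")
  tab_wt <- interaction_frequencies(sys$traj, st, lig)
  # "mutate" the pocket serine: remove its donor flag
  st_mut <- st
  don <- which(st_mut$atoms$resno == 57 & st_mut$atoms$role == "protein")
  st_mut$atoms$donor[don] <- FALSE
  tab_mut <- interaction_frequencies(sys$traj, st_mut, lig)
  d <- compare_fingerprints(tab_wt, tab_mut)
  row <- d[d$resno == 57 & d$type == "HBAcceptor", ]
  expect_equal(nrow(row), 1)
  wt_freq <- tab_wt$raw$frequency[tab_wt$raw$resno == 57 &
                                  tab_wt$raw$type == "HBAcceptor"]
  expect_equal(row$delta, -wt_freq)
  # nothing else moves
  expect_true(all(abs(d$delta[!(d$resno == 57 & d$type == "HBAcceptor")])
                  == 0))
})

test_that("the cross-system report filters at the union maximum", {
  a <- structure(list(raw = data.frame(resno = c(1, 2), type = "Hydrophobic",
                                       frequency = c(80, 10))),
                 class = "fingerprint_table")
  b <- structure(list(raw = data.frame(resno = c(1, 2), type = "Hydrophobic",
                                       frequency = c(20, 25))),
                 class = "fingerprint_table")
  rep <- fingerprint_report(list(A = a, B = b), threshold = 30)
  expect_equal(rep$resno, 1)          # row 2 never exceeds 30 anywhere
  expect_equal(rep$A, 80)
  expect_equal(rep$B, 20)
})
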