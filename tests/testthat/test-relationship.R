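test_that("marker QC applies the missingness, monomorphism and MAF rules", {
  n <- 100
  set.seed(1)
  mk <- function(p) rbinom(n, 6, p)
  Z <- cbind(L1 = mk(0.5), L2 = rep(3, n), L3 = rep(6, n),
             L4 = mk(0.04 / 1), L5 = mk(0.5), L6 = mk(0.3), L7 = mk(0.7),
             L8 = mk(0.5), L9 = mk(0.5), L10 = mk(0.5))
  # L4: force an exact MAF of 0.04 -> mean dosage 0.24
  Z[, "L4"] <- 0; Z[seq_len(24), "L4"] <- 1
  # L8: 15% missing
  Z[seq_len(15), "L8"] <- NA
  pan <- filter_markers(Z)
  expect_equal(unname(pan$removed),
               c(1L, 2L, 1L))   # missing, monomorphic (L2, L3), MAF (L4)
  expect_equal(ncol(pan$Z), 6)
  expect_false("L8" %in% colnames(pan$Z))
  # centred matrix sums to zero per locus when p estimated from the data
  expect_lt(max(abs(colSums(pan$W))), 1e-9)

  # boundary: 11% missing removed, all-equal dosage removed
  Z2 <- cbind(A = c(rep(NA, 11), mk(0.5)[1:89]), B = rep(3, 100),
              C = mk(0.5))
  pan2 <- filter_markers(Z2)
  expect_equal(colnames(pan2$Z), "C")
  expect_error(filter_markers(matrix(3, 10, 2)), "all loci removed")
})

test_that("the genomic matrix matches its closed form and diagonal identity", {
  # two individuals, one locus, dosages (6, 0): W = (3, -3), denom = 1.5
  Z <- matrix(c(6, 0), 2, 1, dimnames = list(c("a", "b"), "L1"))
  G <- G_matrix(filter_markers(Z))
  expect_equal(unname(G$mat), matrix(c(6, -6, -6, 6), 2), tolerance = 1e-12)
  # zero centred matrix gives the zero matrix
  pan0 <- structure(list(Z = matrix(3, 4, 2), W = matrix(0, 4, 2),
                         p = c(0.5, 0.5), denom = 3),
                    class = "dosage_panel")
  expect_true(all(G_matrix(pan0)$mat == 0))
  # mean(diag(G)) = 1 + 5 mean(F), G is PSD, and for a large HW panel the
  # mean diagonal approaches 1
  base <- simulate_founders(150, 500, seed = 11)
  Gf <- G_matrix(filter_markers(base))
  expect_equal(mean(diag(Gf$mat)), 1 + 5 * mean(Gf$F), tolerance = 1e-12)
  expect_equal(mean(diag(Gf$mat)), 1, tolerance = 0.05)
  expect_gt(min(eigen(Gf$mat, only.values = TRUE)$values), -1e-8)
})

test_that("hexaploid pedigree relationships agree with gene dropping", {
  ped <- data.frame(id = c("P1", "P2", "P3", "O1", "O2", "X1"),
                    parent1 = c(NA, NA, NA, "P1", "P1", "O1"),
                    parent2 = c(NA, NA, NA, "P2", "P2", "O2"))
  A <- A_matrix(ped)
  # founders: identity block
  expect_equal(unname(A$mat[1:3, 1:3]), diag(3))
  # parent-offspring and full sibs at the closed-form values
  expect_equal(A$mat["P1", "O1"], 0.5)
  expect_equal(A$mat["O1", "O2"], 0.5)
  Adrop <- gene_drop_A(ped, n_rep = 30000, seed = 3)
  expect_equal(A$mat, Adrop, tolerance = 3e-3)
  # full-sib mating builds up inbreeding: F = A_sd / 10
  expect_equal(A$mat["X1", "X1"], 1 + 5 * 0.05)
  # ordering invariance of theta
  perm <- c(4, 2, 6, 1, 3, 5)
  A2 <- A_matrix(ped[order(perm), ])
  expect_equal(rel_theta(A2), rel_theta(A))
  expect_error(A_matrix(data.frame(id = c("a", "b"), parent1 = c("b", "a"),
                                   parent2 = c(NA, NA))), "cycle")
})

test_that("realized relationships regress on expected relationships with slope near 1", {
  pop <- small_population(U = 800, seed = 19)
  A <- A_matrix(pop$pedigree)
  G <- G_matrix(filter_markers(pop$dosage))
  ids <- rownames(pop$cross$dosage)
  a <- A$mat[ids, ids][upper.tri(diag(length(ids)))]
  g <- G$mat[ids, ids][upper.tri(diag(length(ids)))]
  expect_equal(unname(coef(lm(g ~ a))[2]), 1, tolerance = 0.15)
})

test_that("blending interpolates towards the identity and is recorded", {
  M <- matrix(c(1, 1, 1, 1), 2)
  expect_equal(blend(M, 0.02), matrix(c(1, 0.98, 0.98, 1), 2))
  expect_equal(blend(M, 0), M)
  expect_equal(blend(diag(3), 0.5), diag(3))
  pop <- small_population(seed = 3)
  G <- G_matrix(filter_markers(pop$founders))
  Gb <- blend(G, 0.05)
  expect_equal(Gb$blend_w, 0.05)
  expect_gt(min(eigen(Gb$mat, only.values = TRUE)$values), 0.049)
  expect_error(blend(G, 1.2), "weight")
})
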