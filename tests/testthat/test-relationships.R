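test_that("pedigree A matrix reproduces textbook relationships", {
  ped2 <- as_pedigree(data.frame(id = c("a", "b"), sire = 0, dam = 0))
  expect_equal(unname(build_A(ped2)), diag(2), ignore_attr = TRUE)
  po <- as_pedigree(data.frame(id = c("s", "d", "x"),
                               sire = c(0, 0, "s"), dam = c(0, 0, "d")))
  A <- build_A(po)
  expect_equal(A["s", "x"], 0.5)
  expect_equal(A["x", "x"], 1.0)
  fs <- as_pedigree(data.frame(id = c("s", "d", "x", "y"),
                               sire = c(0, 0, "s", "s"),
                               dam = c(0, 0, "d", "d")))
  Af <- build_A(fs)
  expect_equal(Af["x", "y"], 0.5)
  expect_equal(diag(Af), c(s = 1, d = 1, x = 1, y = 1))
  # selfed-line style inbreeding: offspring of full sibs
  ib <- as_pedigree(data.frame(id = c("s", "d", "x", "y", "z"),
                               sire = c(0, 0, "s", "s", "x"),
                               dam = c(0, 0, "d", "d", "y")))
  expect_equal(build_A(ib)["z", "z"], 1.25)
  expect_error(as_pedigree(data.frame(id = c("x", "s"), sire = c("s", 0),
                                      dam = c(0, 0))),
               "precede")
})

test_that("A from a simulated multi-generation pedigree is positive definite", {
  set.seed(11)
  sim <- small_sim(n_generations = 3)
  A <- build_A(sim$pedigree)
  expect_silent(chol(A))
})

test_that("VanRaden G matrices center and scale correctly", {
  # one individual, one locus, dosage 0 at p = 0.5
  g1 <- matrix(0, 1, 1, dimnames = list("a", "l1"))
  expect_equal(build_G(g1, method = 1, p = 0.5)[1, 1], 2.0)
  # equal locus weights collapse methods 1 and 2
  set.seed(3)
  X <- matrix(rbinom(200 * 50, 2, 0.5), 200, 50,
              dimnames = list(sprintf("i%03d", 1:200), NULL))
  p_half <- rep(0.5, 50)
  expect_equal(build_G(X, 1, p = p_half), build_G(X, 2, p = p_half),
               ignore_attr = TRUE)
  # unrelated panel: mean diagonal near 1
  p <- runif(1000, 0.1, 0.9)
  Xu <- sapply(p, function(pp) rbinom(200, 2, pp))
  rownames(Xu) <- sprintf("i%03d", 1:200)
  expect_equal(mean(diag(build_G(Xu, 1))), 1.0, tolerance = 0.05)
  expect_equal(mean(diag(build_G(Xu, 2))), 1.0, tolerance = 0.05)
  expect_error(build_G(matrix(2, 3, 4, dimnames = list(letters[1:3], NULL))),
               "monomorphic")
  Xna <- X; Xna[1, 1] <- NA
  expect_error(build_G(Xna), "missing")
})

test_that("G methods 1 and 2 nearly agree on common-variant data", {
  set.seed(7)
  sim <- small_sim(n_generations = 1)
  G1 <- build_G(sim$markers, 1)
  G2 <- build_G(sim$markers, 2)
  expect_gt(cor(G1[upper.tri(G1)], G2[upper.tri(G2)]), 0.99)
})

test_that("relationship-variance Me is the reciprocal pair variance", {
  A <- diag(50); rownames(A) <- colnames(A) <- sprintf("i%02d", 1:50)
  expect_error(me_from_relationship_variance(A, A), "zero relationship variance")
  set.seed(5)
  E <- matrix(0, 50, 50)
  E[upper.tri(E)] <- rnorm(sum(upper.tri(E)), sd = sqrt(0.001))
  E <- E + t(E)
  G <- A + E
  dimnames(G) <- dimnames(A)
  expect_equal(me_from_relationship_variance(G, A), 1000, tolerance = 0.15)
  expect_error(me_from_relationship_variance(diag(1), diag(1)), "at least 2")
})

test_that("GEBV decomposition conserves the input and splits G = A case", {
  set.seed(9)
  n <- 30
  A <- diag(n) + 0.1
  rownames(A) <- colnames(A) <- sprintf("i%02d", 1:n)
  gebv <- rnorm(n)
  d0 <- decompose_gebv(gebv, A, A)
  expect_equal(d0$g_A_star, gebv, tolerance = 1e-10)
  expect_equal(d0$g_D, rep(0, n), tolerance = 1e-10)
  sim <- small_sim(n_generations = 2)
  G <- build_G(sim$markers)
  Ap <- build_A(sim$pedigree)
  ids <- rownames(G)
  ebv <- solve_blup(G, sim$phen[, c("id", "value")], 0.4)
  d <- decompose_gebv(ebv$ebv, Ap[ids, ids], G)
  expect_equal(d$g_A_star + d$g_D, ebv$ebv, tolerance = 1e-8)
  # pedigree-tracked and deviation parts trade off against each other
  expect_lt(cor(d$g_A_star, d$g_D), 0)
})

test_that("pedigree and dosage files roundtrip", {
  ped <- as_pedigree(data.frame(id = c("s", "d", "x"), sire = c(0, 0, "s"),
                                dam = c(0, 0, "d"), generation = c(0, 0, 1)))
  f <- tempfile(fileext = ".csv")
  write_pedigree(ped, f)
  expect_equal(as.data.frame(read_pedigree(f)), as.data.frame(ped))
  X <- matrix(c(0, 1, 2, 2, 1, 0), 2, 3,
              dimnames = list(c("a", "b"), c("l1", "l2", "l3")))
  fg <- tempfile(fileext = ".tsv")
  write_dosages(X, fg)
  expect_equal(read_dosages(fg), X)
  # PLINK .raw-style table
  fr <- tempfile(fileext = ".raw")
  writeLines(c("FID IID PAT MAT SEX PHENOTYPE l1_A l2_A",
               "f1 a 0 0 1 -9 0 2",
               "f1 b 0 0 2 -9 1 1"), fr)
  m <- read_dosages(fr)
  expect_equal(m, matrix(c(0, 1, 2, 1), 2, 2,
                         dimnames = list(c("a", "b"), c("l1_A", "l2_A"))))
  K <- build_A(ped)
  fk <- tempfile(fileext = ".tsv")
  write_relationship_matrix(K, fk)
  expect_equal(read_relationship_matrix(fk), K, ignore_attr = TRUE)
})
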