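chain_dag <- function(ids) {
  disease_dag(root = ids[1],
              edges = data.frame(child = head(ids, -1), parent = ids[-1]))
}

test_that("semantic contribution decays along ancestor chains with max rule", {
  expect_equal(semantic_contribution(disease_dag("D"), 0.5), c(D = 1))
  chain <- chain_dag(c("D", "P", "G"))
  expect_equal(semantic_contribution(chain, 0.5), c(D = 1, P = 0.5, G = 0.25))
  expect_equal(semantic_value(chain, 0.5), 1.75)
  # diamond: G reachable at depth 1 and 2 -> max rule keeps 0.5
  diamond <- disease_dag("D", data.frame(
    child = c("D", "D", "P"), parent = c("P", "G", "G")))
  expect_equal(semantic_contribution(diamond, 0.5)[["G"]], 0.5)
  # node floating off the root's ancestor closure is an error
  expect_error(
    semantic_contribution(disease_dag("D", data.frame(child = "X", parent = "Y"))),
    "unreachable")
})

test_that("pairwise semantic similarity matches exhaustive path enumeration", {
  # self-similarity and disjoint cases
  d <- chain_dag(c("D", "P"))
  expect_equal(dss1(d, d, 0.5), 1)
  expect_equal(dss1(chain_dag(c("A", "B")), chain_dag(c("C", "E")), 0.5), 0)
  # two siblings under one parent: (0.5+0.5)/(1.5+1.5)
  d1 <- disease_dag("D1", data.frame(child = "D1", parent = "P"))
  d2 <- disease_dag("D2", data.frame(child = "D2", parent = "P"))
  expect_equal(dss1(d1, d2, 0.5), 1 / 3)
  # 100 random DAG pairs vs the oracle, exactly
  for (s in 1:100) {
    g1 <- random_dag(sample(1:12, 1), seed = s)
    g2 <- random_dag(sample(1:12, 1), seed = s + 1000)
    # overlap node names so intersections are nonempty sometimes
    expect_equal(dss1(g1, g2, 0.7), oracle_dss1(g1, g2, 0.7), tolerance = 1e-12)
    expect_equal(dss1(g1, g1, 0.7), 1, tolerance = 1e-12)
  }
})

test_that("symptom cosine similarity handles signal, orthogonality and zero rows", {
  p <- rbind(a = c(1, 1, 0), b = c(0, 1, 1), c = c(2, 2, 0), d = c(0, 0, 0))
  colnames(p) <- paste0("s", 1:3)
  expect_warning(dss2(p), "all-zero")
  S <- suppressWarnings(dss2(p))
  expect_equal(unname(S["a", "b"]), 0.5)
  expect_equal(unname(S["a", "c"]), 1)    # proportional rows
  expect_equal(unname(S["a", "d"]), 0)    # zero profile
  expect_equal(unname(diag(unclass(S))), rep(1, 4))
  q <- rbind(x = c(1, 0), y = c(0, 1)); colnames(q) <- c("s1", "s2")
  expect_equal(unname(dss2(q)["x", "y"]), 0)
})

test_that("GIP kernel equals the direct definition on random binary matrices", {
  A <- association_matrix(diag(2) * 1,
                          row_labels = c("m1", "m2"), col_labels = c("d1", "d2"))
  K <- gip_kernel(A, "disease")
  expect_equal(unname(K["d1", "d2"]), exp(-2))  # eta = 1, distance^2 = 2
  for (s in 1:20) {
    set.seed(s)
    nm <- sample(3:20, 1); nd <- sample(3:20, 1)
    M <- matrix(rbinom(nm * nd, 1, 0.4), nm, nd,
                dimnames = list(sprintf("m%02d", 1:nm), sprintf("d%02d", 1:nd)))
    if (all(M == 0)) M[1, 1] <- 1
    A <- association_matrix(M)
    expect_lt(max(abs(unclass(gip_kernel(A, "microbe")) - oracle_gip(M))), 1e-12)
    expect_lt(max(abs(unclass(gip_kernel(A, "disease")) - oracle_gip(t(M)))), 1e-12)
  }
  # doubling eta' squares off-diagonal entries
  set.seed(99)
  M <- matrix(rbinom(40, 1, 0.5), 5, 8,
              dimnames = list(paste0("m", 1:5), paste0("d", 1:8)))
  A <- association_matrix(M)
  K1 <- unclass(gip_kernel(A, "microbe", eta_prime = 1))
  K2 <- unclass(gip_kernel(A, "microbe", eta_prime = 2))
  expect_equal(K2, K1 ^ 2, tolerance = 1e-12)
  Z <- matrix(0, 3, 3, dimnames = list(paste0("m", 1:3), paste0("d", 1:3)))
  expect_error(gip_kernel(association_matrix(Z), "microbe"), "bandwidth")
})

test_that("set and functional similarity follow the best-match definition", {
  base <- random_similarity(5, seed = 7, labels = paste0("d", 1:5))
  expect_equal(set_similarity("d1", c("d1", "d3"), base), 1)
  expect_equal(set_similarity("d2", "d4", base), unname(base["d2", "d4"]))
  expect_error(set_similarity("d9", "d1", base), "not indexed")

  # two microbes with singleton sets: score is the single cross similarity
  B <- matrix(c(1, 0, 0, 1), 2, 2,
              dimnames = list(c("mx", "my"), c("d1", "d2")))
  base2 <- similarity_matrix(matrix(c(1, .4, .4, 1), 2, 2,
                                    dimnames = list(c("d1", "d2"), c("d1", "d2"))))
  S <- functional_similarity(B, base2)
  expect_equal(unname(S["mx", "my"]), 0.4)
  # identical sets with unit-diagonal base give 1
  B2 <- matrix(1, 2, 2, dimnames = dimnames(B))
  expect_equal(unname(functional_similarity(B2, base2)["mx", "my"]), 1)
  # random instances vs the set-definition oracle
  for (s in 1:15) {
    set.seed(s)
    nmic <- sample(3:8, 1); nd <- 5
    M <- matrix(rbinom(nmic * nd, 1, 0.5), nmic, nd,
                dimnames = list(sprintf("m%d", 1:nmic), paste0("d", 1:5)))
    sets <- apply(M, 1, function(r) colnames(M)[r == 1], simplify = FALSE)
    S <- suppressWarnings(functional_similarity(M, base))
    expect_equal(matrix(S, nrow(S)), oracle_dfs(sets, unclass(base)),
                 tolerance = 1e-12)
  }
})

test_that("two-source merge averages double hits and keeps single hits", {
  l <- list(c("m1", "m2"), c("m1", "m2"))
  Sa <- similarity_matrix(matrix(c(1, .6, .6, 1), 2, 2, dimnames = l))
  Sb0 <- similarity_matrix(matrix(c(1, 0, 0, 1), 2, 2, dimnames = l))
  Sb <- similarity_matrix(matrix(c(1, .4, .4, 1), 2, 2, dimnames = l))
  expect_equal(unname(merge_similarities(Sa, Sb)["m1", "m2"]), 0.5)
  expect_equal(unname(merge_similarities(Sa, Sb0)["m1", "m2"]), 0.6)
  expect_equal(unname(merge_similarities(Sb0, Sb0)["m1", "m2"]), 0)
})

test_that("every similarity family yields symmetric [0,1] matrices", {
  set.seed(21)
  M <- matrix(rbinom(60, 1, 0.3), 10, 6,
              dimnames = list(sprintf("m%02d", 1:10), sprintf("d%d", 1:6)))
  M[rowSums(M) == 0, 1] <- 1
  A <- association_matrix(M)
  dags <- lapply(setNames(nm = colnames(M)), function(d) random_dag(6, seed = match(d, colnames(M))))
  for (d in names(dags)) dags[[d]]$root <- dags[[d]]$nodes[1]
  mats <- list(
    gip_kernel(A, "microbe"), gip_kernel(A, "disease"),
    suppressWarnings(functional_similarity(M, gip_kernel(A, "disease"))),
    dss2(matrix(runif(18), 6, 3, dimnames = list(colnames(M), paste0("s", 1:3))))
  )
  for (S in mats) {
    expect_lt(max(abs(unclass(S) - t(unclass(S)))), 1e-12)
    expect_gte(min(S), 0); expect_lte(max(S), 1)
  }
})
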