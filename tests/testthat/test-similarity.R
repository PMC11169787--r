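test_that("semantic profiles match hand-derived worked cases", {
  # isolated node
  iso <- make_dag(matrix(character(0), 0, 2), extra_nodes = "a")
  p <- semantic_profile(iso, "a", 0.5)
  expect_equal(p$contributions, c(a = 1))
  expect_equal(p$semantic_value, 1)

  # chain r -> p -> a
  chain <- make_dag(c("r", "p", "p", "a"))
  pa <- semantic_profile(chain, "a", 0.5)
  expect_equal(pa$contributions[["p"]], 0.5)
  expect_equal(pa$contributions[["r"]], 0.25)
  expect_equal(pa$semantic_value, 1.75)

  # diamond r -> p1 -> a, r -> p2 -> a: max over paths, counted once
  diamond <- make_dag(c("r", "p1", "r", "p2", "p1", "a", "p2", "a"))
  pd <- semantic_profile(diamond, "a", 0.5)
  expect_equal(unname(pd$contributions[c("p1", "p2", "r")]), c(0.5, 0.5, 0.25))
  expect_equal(pd$semantic_value, 2.25)

  expect_error(semantic_profile(chain, "zzz", 0.5), "not in DAG")
})

test_that("pairwise similarity matches worked values and basic identities", {
  sib <- make_dag(c("p", "a", "p", "b"))
  pa <- semantic_profile(sib, "a", 0.5)
  pb <- semantic_profile(sib, "b", 0.5)
  expect_equal(disease_semantic_similarity(pa, pb), 1 / 3)
  expect_equal(disease_semantic_similarity(pb, pa), 1 / 3)
  expect_equal(disease_semantic_similarity(pa, pa), 1)

  # disjoint components
  two <- make_dag(c("p", "a", "q", "b"))
  expect_equal(disease_semantic_similarity(semantic_profile(two, "a", 0.5),
                                           semantic_profile(two, "b", 0.5)), 0)

  # mismatched delta is an error
  expect_error(disease_semantic_similarity(
    semantic_profile(sib, "a", 0.5), semantic_profile(sib, "b", 0.4)),
    "delta")
})

test_that("semantic profile equals exhaustive path-enumeration oracle", {
  for (seed in 1:25) {
    dag <- generate_random_dag(sample(c(5L, 12L, 20L), 1L),
                               max_parents = 3L, seed = seed)
    targets <- head(dag$nodes, 3L)
    for (a in targets) {
      prof <- semantic_profile(dag, a, 0.5)
      orac <- oracle_profile(dag, a, 0.5)
      expect_equal(prof$contributions[sort(names(prof$contributions))],
                   orac$contributions[sort(names(orac$contributions))],
                   tolerance = 1e-12)
      expect_equal(prof$semantic_value, orac$semantic_value,
                   tolerance = 1e-12)
    }
  }
})

test_that("disease similarity matrix is valid and matches pairwise calls", {
  chain <- make_dag(c("r", "p", "p", "a"))
  m <- disease_similarity_matrix(chain, c("r", "p", "a"), 0.5)
  for (i in 1:3) for (j in 1:3) {
    expect_equal(m[i, j],
                 oracle_similarity(chain, rownames(m)[i], colnames(m)[j], 0.5),
                 tolerance = 1e-12)
  }

  expect_equal(disease_similarity_matrix(chain, "a", 0.5),
               matrix(1, 1, 1, dimnames = list("a", "a")))

  dag <- generate_random_dag(25L, seed = 99L)
  ms <- disease_similarity_matrix(dag, dag$nodes, 0.5)
  expect_lt(max(abs(ms - t(ms))), 1e-12)
  expect_true(all(diag(ms) == 1))
  expect_true(all(ms >= 0 & ms <= 1))

  # diseases missing from the DAG: self-only similarity with a warning
  expect_warning(mm <- disease_similarity_matrix(chain, c("a", "ghost"), 0.5),
                 "missing")
  expect_equal(mm["a", "ghost"], 0)
  expect_equal(mm["ghost", "ghost"], 1)
})

test_that("miRNA functional similarity: worked toy and invariants", {
  sib <- make_dag(c("p", "a", "p", "b"))
  catg <- make_catalog(c("u", "v"), c("a", "b"), c(1L, 1L, 2L, 1L, 2L, 2L))
  dsim <- disease_similarity_matrix(sib, c("a", "b"), 0.5)
  ms <- mirna_functional_similarity(catg, dsim)
  expect_equal(ms["u", "v"], 7 / 9)  # DT(u)={a}, DT(v)={a,b}, S(a,b)=1/3

  # identical nonempty disease sets -> 1
  cat_same <- make_catalog(c("u", "v"), c("a", "b"),
                           c(1L, 1L, 1L, 2L, 2L, 1L, 2L, 2L))
  expect_equal(mirna_functional_similarity(cat_same, dsim)["u", "v"], 1)

  # disjoint DAG components -> 0; empty disease set -> self-only
  two <- make_dag(c("p", "a", "q", "b"))
  dsim2 <- disease_similarity_matrix(two, c("a", "b"), 0.5)
  cat2 <- make_catalog(c("u", "v", "w"), c("a", "b"), c(1L, 1L, 2L, 2L))
  ms2 <- suppressMessages(mirna_functional_similarity(cat2, dsim2))
  expect_equal(ms2["u", "v"], 0)
  expect_equal(ms2["w", "w"], 1)
  expect_equal(ms2["w", "u"], 0)

  # invariants on a random planted world
  world <- generate_planted(planted_spec(n_mirnas = 15L, n_diseases = 12L,
                                         n_groups = 3L, seed = 5L))
  dsim3 <- disease_similarity_matrix(world$dag, world$catalog$disease_names, 0.5)
  ms3 <- suppressMessages(
    mirna_functional_similarity(world$catalog, dsim3))
  expect_lt(max(abs(ms3 - t(ms3))), 1e-12)
  expect_true(all(diag(ms3) == 1))
  expect_true(all(ms3 >= 0 & ms3 <= 1))
})
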