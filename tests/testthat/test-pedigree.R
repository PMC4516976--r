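test_that("relationship classification matches definitions and the path-enumeration oracle", {
  ped <- fixture_ped3gen()
  expect_equal(classify_relationship(ped, "gf", "f1"), "parent-offspring")
  expect_equal(classify_relationship(ped, "f1", "c11"), "parent-offspring")
  expect_equal(classify_relationship(ped, "c11", "c21"), "first-cousin")
  expect_equal(classify_relationship(ped, "f1", "f2"), "sibling")
  expect_equal(classify_relationship(ped, "gf", "c12"), "grandparent-grandchild")
  expect_equal(classify_relationship(ped, "u3", "c21"), "avuncular")
  expect_equal(classify_relationship(ped, "gf", "gm"), "spouse")
  expect_equal(classify_relationship(ped, "s1", "s2"), "other")
  expect_equal(classify_relationship(ped, "s1", "c21"), "other")

  ## every pair against the independent oracle, and symmetry
  ids <- ped$id
  for (a in seq_along(ids)) for (b in seq_along(ids)) {
    if (a >= b) next
    got <- classify_relationship(ped, ids[a], ids[b])
    expect_equal(got, oracle_classify(ped, ids[a], ids[b]),
                 info = paste(ids[a], ids[b]))
    expect_equal(got, classify_relationship(ped, ids[b], ids[a]))
  }
})

test_that("relationship_pairs covers all pairs exactly once", {
  ped <- fixture_ped3gen()
  pr <- relationship_pairs(ped)
  expect_equal(nrow(pr), choose(nrow(ped), 2))
  expect_false(any(duplicated(t(apply(pr[, 1:2], 1, sort)))))
})

test_that("kinship coefficients take their closed-form values and agree with pair classes", {
  ped <- fixture_ped3gen()
  expect_equal(kinship(ped, "gf", "gf"), 0.5)
  expect_equal(kinship(ped, "gf", "f1"), 0.25)
  expect_equal(kinship(ped, "f1", "f2"), 0.25)
  expect_equal(kinship(ped, "u3", "c21"), 0.125)
  expect_equal(kinship(ped, "gf", "c11"), 0.125)
  expect_equal(kinship(ped, "c11", "c21"), 0.0625)
  expect_equal(kinship(ped, "gf", "gm"), 0)
  expect_equal(kinship(ped, "s1", "s2"), 0)

  closed <- c("parent-offspring" = 0.25, sibling = 0.25, avuncular = 0.125,
              "grandparent-grandchild" = 0.125, "first-cousin" = 0.0625,
              spouse = 0)
  pr <- relationship_pairs(ped)
  K <- kinship_matrix(ped)
  for (k in seq_len(nrow(pr))) {
    cls <- pr$class[k]
    if (cls %in% names(closed))
      expect_equal(K[pr$id1[k], pr$id2[k]], unname(closed[cls]),
                   info = paste(pr$id1[k], pr$id2[k], cls))
  }
  ## no common ancestor and distinct -> kinship 0
  expect_true(all(K[c("s1", "s2"), c("gf", "gm")] == 0))
})

test_that("first-cousin kinship is confirmed by gene-dropping Monte Carlo", {
  ped <- fixture_ped3gen()
  set.seed(99)
  reps <- 4000
  g <- replicate(reps, {
    x <- simulate_genotypes(list(ped), maf = 0.5)
    x[match(c("c11", "c21"), ped$id)]
  })
  ## allele-count correlation under HWE equals twice the kinship coefficient
  expect_equal(cor(g[1, ], g[2, ]), 2 * 0.0625, tolerance = 0.35)
})

test_that("pedigree construction and lookups reject invalid input", {
  expect_error(classify_relationship(fixture_ped3gen(), "gf", "nobody"),
               class = "jx_identifier_error")
  expect_error(kinship(fixture_ped3gen(), "zz", "gf"),
               class = "jx_identifier_error")
  expect_error(classify_relationship(fixture_ped3gen(), "gf", "gf"),
               class = "jx_argument_error")
  ## dangling parent
  expect_error(pedigree("F", id = c("a", "b"), father_id = c(NA, "zz"),
                        mother_id = c(NA, "a"), sex = c(2, 1),
                        age = c(40, 20)),
               class = "jx_identifier_error")
  ## exactly one parent known
  expect_error(pedigree("F", id = c("a", "b"), father_id = c(NA, NA),
                        mother_id = c(NA, "a"), sex = c(2, 1),
                        age = c(40, 20)),
               class = "jx_pedigree_error")
})
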