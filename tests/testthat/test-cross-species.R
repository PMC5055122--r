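# small deterministic MAP/binary fixtures for the filter tests
filter_fixture <- function(seed = 3, n_genes = 40, kA = 8, kB = 7) {
  set.seed(seed)
  genesA <- sprintf("a%02d", seq_len(n_genes))
  genesB <- sprintf("b%02d", seq_len(n_genes))
  mapA <- matrix(round(exp(rnorm(n_genes * kA, 0, 1.2)), 2), n_genes,
                 dimnames = list(genesA, paste0("A", seq_len(kA))))
  mapB <- matrix(round(exp(rnorm(n_genes * kB, 0, 1.2)), 2), n_genes,
                 dimnames = list(genesB, paste0("B", seq_len(kB))))
  binA <- matrix(rbinom(n_genes * kA, 1, 0.3), n_genes,
                 dimnames = dimnames(mapA))
  binB <- matrix(rbinom(n_genes * kB, 1, 0.3), n_genes,
                 dimnames = dimnames(mapB))
  hom <- data.frame(gene1 = genesA, gene2 = genesB, stringsAsFactors = FALSE)
  list(mapA = mapA, mapB = mapB, binA = binA, binB = binB, hom = hom)
}

test_that("comparison-gene filter equals its set-comprehension oracle", {
  fx <- filter_fixture()
  res <- filter_comparison_genes(fx$mapA, fx$mapB, fx$binA, fx$binB, fx$hom)
  # independent oracle: literal per-condition comprehension
  keep <- c()
  for (i in seq_len(nrow(fx$hom))) {
    a <- fx$hom$gene1[i]; b <- fx$hom$gene2[i]
    c1 <- sum(fx$binA[a, ]) >= 1 && sum(fx$binB[b, ]) >= 1
    c2 <- sum(fx$binA[a, ]) < 6 || sum(fx$binB[b, ]) < 6
    c3 <- (max(fx$mapA[a, ]) > 1.5 && min(fx$mapA[a, ]) < 0.25) ||
          (max(fx$mapB[b, ]) > 1.5 && min(fx$mapB[b, ]) < 0.25)
    if (c1 && c2 && c3) keep <- c(keep, a)
  }
  expect_setequal(res$pairs$gene1, keep)
})

test_that("the filter conditions apply per the stated bounds", {
  fx <- filter_fixture(seed = 4)
  # gene significant nowhere in A -> excluded
  fx$binA["a01", ] <- 0L
  fx$binB["b01", ] <- 1L
  fx$mapA["a01", ] <- c(5, rep(0.1, ncol(fx$mapA) - 1))
  res <- filter_comparison_genes(fx$mapA, fx$mapB, fx$binA, fx$binB, fx$hom)
  expect_false("a01" %in% res$pairs$gene1)

  # significant in 6 types in both species -> excluded; 6 and 3 -> included
  fx2 <- filter_fixture(seed = 5)
  fx2$binA["a02", ] <- c(rep(1L, 6), rep(0L, ncol(fx2$binA) - 6))
  fx2$binB["b02", ] <- c(rep(1L, 6), rep(0L, ncol(fx2$binB) - 6))
  fx2$binA["a03", ] <- c(rep(1L, 6), rep(0L, ncol(fx2$binA) - 6))
  fx2$binB["b03", ] <- c(rep(1L, 3), rep(0L, ncol(fx2$binB) - 3))
  for (g in c("a02", "a03")) fx2$mapA[g, ] <- c(5, rep(0.1, ncol(fx2$mapA) - 1))
  res2 <- filter_comparison_genes(fx2$mapA, fx2$mapB, fx2$binA, fx2$binB,
                                  fx2$hom)
  expect_false("a02" %in% res2$pairs$gene1)
  expect_true("a03" %in% res2$pairs$gene1)

  # non-bijective homolog rows are dropped and counted
  hom_dup <- rbind(fx$hom, data.frame(gene1 = "a05", gene2 = "zzz"))
  res3 <- filter_comparison_genes(fx$mapA, fx$mapB, fx$binA, fx$binB, hom_dup)
  expect_equal(res3$n_dropped_non_bijective, 2)
  expect_false("a05" %in% res3$pairs$gene1)
})

test_that("similarity matrix and mutual best matches behave as defined", {
  # identical matrices: matched diagonal all 1
  set.seed(6)
  m <- matrix(exp(rnorm(200)), 20, 10,
              dimnames = list(sprintf("g%02d", 1:20), paste0("T", 1:10)))
  pairs <- data.frame(gene1 = rownames(m), gene2 = rownames(m))
  S <- similarity_matrix(m, m, pairs)
  expect_equal(unname(diag(S$S)), rep(1, 10))
  # a common affine rescaling of both species leaves S unchanged
  # (Pearson invariance under shared positive-affine maps)
  m2 <- m * 1.7 + 0.4
  S2 <- similarity_matrix(m2, m2, pairs)
  expect_equal(S$S, S2$S)

  S3 <- matrix(c(0.9, 0.2, 0.1, 0.8), 2, byrow = TRUE,
               dimnames = list(c("h1", "h2"), c("m1", "m2")))
  mm <- mutual_best_matches(S3)
  expect_equal(nrow(mm), 2)
  expect_setequal(paste(mm$typeA, mm$typeB), c("h1 m1", "h2 m2"))
  # a row max that is not a column max yields no match for that row
  S4 <- matrix(c(0.9, 0.5, 0.95, 0.1), 2, byrow = TRUE,
               dimnames = list(c("h1", "h2"), c("m1", "m2")))
  mm4 <- mutual_best_matches(S4)
  expect_false("h1" %in% mm4$typeA)
  # symmetry: swapping species transposes the pair set
  mm_t <- mutual_best_matches(t(S3))
  expect_setequal(paste(mm_t$typeA, mm_t$typeB), c("m1 h1", "m2 h2"))
  expect_error(similarity_matrix(m[1:5, ], m[1:5, ], pairs[1:5, ]),
               ">= 10 gene pairs")
})

test_that("planted type correspondences are recovered end to end", {
  spec <- synthetic_spec(n_genes = 600, n_cells = 300, n_types = 10,
                         base_mean = 0.5, marker_fold = 10,
                         markers_per_type = 20, seed = 31)
  sp <- make_species_pair(spec, n_shared_types = 10, divergence = 0.3)
  profiles <- function(s) {
    labs <- s$truth$type_of_cell
    sapply(colnames(s$truth$mean_matrix), function(t)
      rowMeans(s$counts[, names(labs)[labs == t], drop = FALSE]))
  }
  pa <- profiles(sp$species1)
  pb <- profiles(sp$species2)
  fl <- filter_comparison_genes(pa, pb, (pa > 1.5) * 1L, (pb > 1.5) * 1L,
                                sp$truth$homolog_map)
  S <- similarity_matrix(pa, pb, fl$pairs)
  mm <- mutual_best_matches(S)
  found <- merge(mm, sp$truth$planted_matches,
                 by.x = c("typeA", "typeB"), by.y = c("type1", "type2"))
  expect_equal(nrow(found), 10)
  expect_equal(nrow(mm), 10)
})

test_that("half-sampling time matches closed forms", {
  # symmetric ages: t* at the center
  set.seed(9)
  a <- 13.5 + c(rnorm(300, 0, 1))
  a <- c(a, 27 - a)    # force exact symmetry around 13.5
  expect_lt(abs(half_sampling_time(a) - 13.5), 0.05)
  # uniform[11.5, 18.5]: median 15
  u <- runif(500, 11.5, 18.5)
  expect_lt(abs(half_sampling_time(u) - 15), 0.2)
  # translation equivariance
  expect_equal(half_sampling_time(u + 2.5), half_sampling_time(u) + 2.5,
               tolerance = 1e-6)
  # degenerate: identical ages
  expect_equal(half_sampling_time(rep(12, 10)), 12)
  expect_error(half_sampling_time(c(1, 2)), ">= 5")
})
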