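test_that("otu_table validates counts and identifiers", {
  m <- matrix(1:4, 2, 2, dimnames = list(c("a", "b"), c("x", "y")))
  expect_s3_class(otu_table(m), "otu_table")
  m2 <- m; m2[1, 2] <- -1
  expect_error(otu_table(m2), "non-negative.*'a'.*'y'")
  m3 <- m; rownames(m3) <- c("a", "a")
  expect_error(otu_table(m3), "duplicate sample")
  m4 <- m; m4[2, 1] <- 2.5
  expect_error(otu_table(m4), "non-negative")
})

test_that("read/write round-trips, both orientations", {
  tab <- toy_table(3, 5, seed = 7)
  f <- withr::local_tempfile(fileext = ".tsv")
  write_otu_table(tab, f)
  back <- suppressMessages(read_otu_table(f))
  expect_identical(unclass(back), unclass(tab))

  # taxonomy forces the OTUs-in-rows dialect
  tax <- setNames(paste0("King;Phy", seq_len(5)), colnames(tab))
  tabt <- otu_table(unclass(tab), taxonomy = tax)
  write_otu_table(tabt, f)
  back2 <- suppressMessages(read_otu_table(f, orientation = "otus_in_rows"))
  expect_equal(unclass(back2), unclass(tab), ignore_attr = "taxonomy")
  expect_identical(otu_taxonomy(back2), tax)

  # non-numeric cell is a hard error naming the cell
  writeLines(c("sample_id\to1\to2", "s1\t3\tfoo", "s2\t1\t2"), f)
  expect_error(suppressMessages(read_otu_table(f)), "non-numeric.*s1.*o2")
})

test_that("rarefy hits depth exactly, without replacement, deterministically", {
  tab <- toy_table(5, 20, lambda = 30, seed = 1)
  r <- rarefy(tab, 100, seed = 9)
  expect_true(all(rowSums(unclass(r)) == 100))
  expect_true(all(unclass(r) <= unclass(tab)))       # without replacement
  expect_identical(unclass(rarefy(tab, 100, seed = 9)), unclass(r))
  expect_false(identical(unclass(rarefy(tab, 100, seed = 10)), unclass(r)))
  # sample at exactly depth is untouched
  tot <- rowSums(unclass(tab))
  r2 <- rarefy(tab, min(tot), seed = 1)
  i <- which.min(tot)
  expect_identical(unclass(r2)[i, ], unclass(tab)[i, ])
  # depth 1: a single surviving read
  r3 <- rarefy(tab, 1, seed = 4)
  expect_true(all(rowSums(unclass(r3)) == 1))
  expect_true(all(rowSums(unclass(r3) > 0) == 1))
  expect_error(rarefy(tab, max(tot) + 1, seed = 1), "shallower")
})

test_that("rarefy matches the hypergeometric expectation", {
  counts <- c(a = 50, b = 30, c = 15, d = 5)
  tab <- otu_table(matrix(counts, 1, 4, dimnames = list("s1", names(counts))))
  depth <- 40
  reps <- 1000
  draws <- vapply(seq_len(reps), function(s)
    unclass(rarefy(tab, depth, seed = s))[1, ], numeric(4))
  exp_counts <- depth * counts / sum(counts)
  # hypergeometric variance per OTU
  N <- sum(counts)
  v <- depth * (counts / N) * (1 - counts / N) * (N - depth) / (N - 1)
  se <- sqrt(v / reps)
  expect_true(all(abs(rowMeans(draws) - exp_counts) <= 3 * se))
})

test_that("alpha diversity matches hand calculations and vegan", {
  # uniform sample, no singletons
  t1 <- otu_table(matrix(c(5, 5, 5, 5), 1, 4,
                         dimnames = list("s", paste0("o", 1:4))))
  a1 <- alpha_diversity(t1)
  expect_equal(a1$richness, 4)
  expect_equal(a1$shannon, log(4))
  expect_equal(a1$pielou, 1)
  expect_equal(a1$simpson_1_minus_D, 0.75)
  expect_equal(a1$goods_coverage, 1)

  # hand-derived Chao1 and coverage for counts [1,1,2]
  t2 <- otu_table(matrix(c(1, 1, 2), 1, 3, dimnames = list("s", paste0("o", 1:3))))
  a2 <- alpha_diversity(t2)
  expect_equal(a2$chao1, 3.5)
  expect_equal(a2$goods_coverage, 0.5)

  # degenerate single-OTU sample
  t3 <- otu_table(matrix(10, 1, 1, dimnames = list("s", "o1")))
  a3 <- alpha_diversity(t3)
  expect_equal(a3$shannon, 0)
  expect_equal(a3$simpson_1_minus_D, 0)
  expect_true(is.na(a3$pielou))

  # chao1/ACE against vegan::estimateR on a random table
  tab <- toy_table(4, 60, lambda = 3, seed = 12)
  a <- alpha_diversity(tab)
  vg <- t(vegan::estimateR(unclass(tab)))
  expect_equal(a$chao1, unname(vg[, "S.chao1"]), tolerance = 1e-10)
  expect_equal(a$ace, unname(vg[, "S.ACE"]), tolerance = 1e-10)
  expect_gte(min(a$chao1 - a$richness), 0)
  # row permutation leaves per-sample values unchanged
  perm <- c(3, 1, 4, 2)
  ap <- alpha_diversity(tab[perm, ])
  expect_equal(ap, a[perm, ])
})

test_that("rarefaction curve: analytic equals vegan and Monte Carlo", {
  tab <- toy_table(3, 40, lambda = 4, seed = 3)
  tot <- min(rowSums(unclass(tab)))
  depths <- c(1, 10, 50, tot)
  rc <- rarefaction_curve(tab, depths, mode = "analytic")
  expect_equal(unname(rc[, "1"]), rep(1, 3))
  # at d = N the expectation is S_obs exactly (single-sample table)
  one <- tab[1, ]
  N1 <- sum(unclass(one))
  rc1 <- rarefaction_curve(one, N1, mode = "analytic")
  expect_equal(unname(rc1[1, 1]), sum(unclass(one) > 0), tolerance = 1e-9)
  # monotone non-decreasing in depth
  expect_true(all(diff(t(rc)) >= -1e-9))
  # vegan::rarefy implements the same expectation
  vg <- vegan::rarefy(unclass(tab), 10)
  expect_equal(unname(rc[, "10"]), as.numeric(vg), tolerance = 1e-8,
               ignore_attr = TRUE)
  # Monte Carlo agrees within 3 standard errors
  mc <- rarefaction_curve(tab, 10, mode = "montecarlo", reps = 1000, seed = 5)
  expect_true(all(abs(mc[, 1] - rc[, "10"]) < 3 * sqrt(3 / 1000) * 3))
  expect_error(rarefaction_curve(tab, max(rowSums(unclass(tab))) + 1), "exceeds")
})

test_that("shared_otu_counts enumerates Venn regions", {
  m <- matrix(0, 4, 3, dimnames = list(paste0("s", 1:4), paste0("o", 1:3)))
  m[1:2, 1] <- 1; m[1:3, 2] <- 1; m[3:4, 3] <- 1
  tab <- otu_table(m)
  g <- setNames(c("A", "A", "B", "B"), rownames(m))
  v <- shared_otu_counts(tab, g)
  expect_equal(unname(v$unique["A"]), 1L)   # o1 only in A
  expect_equal(unname(v$unique["B"]), 1L)   # o3 only in B
  expect_equal(v$shared_all, 1L)            # o2 in both
  expect_equal(v$total, 3L)
  # identical groups: everything shared
  g2 <- setNames(c("A", "B", "A", "B"), rownames(m))
  m2 <- matrix(1, 4, 3, dimnames = dimnames(m))
  v2 <- shared_otu_counts(otu_table(m2), g2)
  expect_equal(v2$shared_all, 3L)
  expect_true(all(v2$unique == 0))
  expect_error(shared_otu_counts(tab, g[1:2]), "missing")
})

test_that("aggregate_taxonomy shares sum to 1 and pad shallow lineages", {
  m <- matrix(c(4, 4, 2, 6, 0, 10), 2, 3,
              dimnames = list(c("s1", "s2"), c("o1", "o2", "o3")))
  tax <- c(o1 = "Euk;Alveolata", o2 = "Euk;Stramenopiles", o3 = "Euk")
  tab <- otu_table(m, taxonomy = tax)
  ag <- aggregate_taxonomy(tab, rank = 2)
  expect_equal(colSums(ag$abundance_share), c(s1 = 1, s2 = 1))
  expect_equal(colSums(ag$richness_share), c(s1 = 1, s2 = 1))
  expect_true("unclassified" %in% rownames(ag$abundance_share))
  expect_equal(ag$abundance_share["unclassified", "s2"], 10 / 20)
  ag1 <- aggregate_taxonomy(tab, rank = 1)
  expect_equal(unname(ag1$abundance_share["Euk", ]), c(1, 1))
  expect_warning(aggregate_taxonomy(otu_table(m)), "unclassified")
})
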