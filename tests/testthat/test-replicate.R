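iv <- function(...) {
  m <- matrix(c(...), ncol = 2, byrow = TRUE)
  tibble::tibble(chrom = "chr1", start = as.integer(m[, 1]),
                 end = as.integer(m[, 2]))
}

test_that("control exclusion removes overlapping case items only", {
  case <- iv(0, 50000, 100000, 150000)
  ctrl <- iv(40000, 60000)
  out <- exclude_control_outliers(case, ctrl)
  expect_identical(out, case[2, ])

  # empty controls leave the case set unchanged
  expect_identical(exclude_control_outliers(case, case[0, ]), case)

  # output is always a subset of the input
  set.seed(21)
  for (i in 1:10) {
    a <- random_intervals(8)
    b <- random_intervals(5)
    out <- exclude_control_outliers(a, b)
    expect_true(all(paste(out$start, out$end) %in% paste(a$start, a$end)))
  }

  # site-level exclusion degenerates to identical positions
  sa <- iv(10, 11, 20, 21)
  expect_identical(nrow(exclude_control_outliers(sa, iv(10, 11))), 1L)
  expect_identical(nrow(exclude_control_outliers(sa, iv(11, 12))), 2L)
})

test_that("interval merge respects half-open semantics", {
  expect_identical(merge_overlapping(iv(0, 50000, 25000, 75000)),
                   iv(0, 75000))
  expect_identical(merge_overlapping(iv(0, 10, 10, 20)), iv(0, 10, 10, 20))
  disjoint <- iv(0, 5, 100, 110)
  expect_identical(merge_overlapping(disjoint), disjoint)

  set.seed(22)
  for (i in 1:20) {
    x <- random_intervals(10)
    expect_identical(merge_overlapping(x), oracle_merge(x))
  }
})

test_that("intersection across comparisons yields exclusive Venn regions", {
  s <- iv(0, 100, 500, 600)
  ident <- intersect_across(list(A = s, B = s, C = s))
  expect_true(all(ident$region == "A&B&C"))

  dis <- intersect_across(list(A = iv(0, 10), B = iv(100, 110),
                               C = iv(200, 210)))
  expect_setequal(dis$region, c("A", "B", "C"))

  set.seed(23)
  for (i in 1:10) {
    sets <- list(A = random_intervals(6), B = random_intervals(6),
                 C = random_intervals(6))
    got <- intersect_across(sets)
    merged <- oracle_merge(dplyr::bind_rows(sets))
    expect_identical(got[, c("chrom", "start", "end")], merged)
    # brute-force membership: any shared base
    for (r in seq_len(nrow(got))) {
      for (nm in names(sets)) {
        ol <- any(pmin(got$end[r], sets[[nm]]$end) -
                    pmax(got$start[r], sets[[nm]]$start) > 0)
        expect_identical(got[[nm]][r], ol)
      }
    }
  }
})

test_that("gene proximity uses an inclusive distance boundary", {
  genes <- tibble::tibble(gene_id = "g1", chrom = "chr1",
                          start = 100000L, end = 110000L)
  inside <- iv(105000, 105001)
  expect_identical(genes_near(inside, genes)$distance_bp, 0L)
  # site exactly 25 kb upstream of the gene start (gap = 25000 bases)
  at_edge <- iv(74999, 75000)
  expect_identical(nrow(genes_near(at_edge, genes, 25000L)), 1L)
  beyond <- iv(74998, 74999)
  expect_identical(nrow(genes_near(beyond, genes, 25000L)), 0L)
  # absent chromosome yields no hits
  other <- tibble::tibble(chrom = "chr2", start = 100000L, end = 100001L)
  expect_identical(nrow(genes_near(other, genes)), 0L)

  set.seed(24)
  genes2 <- dplyr::mutate(random_intervals(6),
                          gene_id = sprintf("g%d", 1:6), strand = "+")
  items <- random_intervals(15)
  hits <- genes_near(items, genes2, max_dist_bp = 100L)
  # brute-force all-pairs scan
  want <- list()
  for (i in seq_len(nrow(items))) for (j in seq_len(nrow(genes2))) {
    gap <- oracle_gap(items$start[i], items$end[i],
                      genes2$start[j], genes2$end[j])
    if (gap <= 100L)
      want[[length(want) + 1L]] <- paste(items$start[i], genes2$gene_id[j])
  }
  expect_setequal(paste(hits$start, hits$gene_id), unlist(want))
})

test_that("Venn arithmetic reproduces the three-way worked example", {
  # totals 29 / 21 / 28 with exclusive pairwise overlaps 6 / 8 / 4 and
  # triple overlap 9; inclusion-exclusion gives union 42, shared >= 2 = 27
  triple <- sprintf("t%02d", 1:9)
  ab <- sprintf("ab%d", 1:6); ac <- sprintf("ac%d", 1:8); bc <- sprintf("bc%d", 1:4)
  a_only <- sprintf("a%d", seq_len(29 - 9 - 6 - 8))
  b_only <- sprintf("b%d", seq_len(21 - 9 - 6 - 4))
  c_only <- sprintf("c%d", seq_len(28 - 9 - 8 - 4))
  sets <- list(A = c(triple, ab, ac, a_only),
               B = c(triple, ab, bc, b_only),
               C = c(triple, ac, bc, c_only))
  expect_identical(lengths(sets), c(A = 29L, B = 21L, C = 28L))
  rep <- classify_parallelism(sets, level = "gene")
  expect_identical(rep$union_size, 42L)
  expect_identical(rep$shared_multi, 27L)
  expect_identical(rep$shared_all, 9L)
  v <- rep$venn
  expect_identical(v$count[v$region == "A&B"], 6L)
  expect_identical(v$count[v$region == "A&C"], 8L)
  expect_identical(v$count[v$region == "B&C"], 4L)
  expect_identical(v$count[v$region == "A&B&C"], 9L)
  expect_identical(sum(v$count), rep$union_size)
})

test_that("disjoint and random gene sets match exhaustive enumeration", {
  dis <- classify_parallelism(list(A = c("x", "y"), B = "z", C = "w"),
                              level = "gene")
  expect_identical(dis$union_size, 4L)
  expect_identical(dis$shared_multi, 0L)

  set.seed(25)
  for (i in 1:10) {
    univ <- sprintf("g%02d", 1:30)
    sets <- list(A = sample(univ, 12), B = sample(univ, 8),
                 C = sample(univ, 15))
    rep <- classify_parallelism(sets, level = "gene")
    # exhaustive membership enumeration
    n_in <- vapply(univ, function(g)
      sum(vapply(sets, function(s) g %in% s, logical(1))), integer(1))
    expect_identical(rep$union_size, sum(n_in >= 1L))
    expect_identical(rep$shared_multi, sum(n_in >= 2L))
    expect_identical(rep$shared_all, sum(n_in == 3L))
    expect_identical(sum(rep$venn$count), rep$union_size)
  }
})

test_that("snp-level classification works on interval sets", {
  sets <- list(A = iv(10, 11, 50, 51), B = iv(10, 11), C = iv(90, 91))
  rep <- classify_parallelism(sets, level = "snp")
  expect_identical(rep$union_size, 3L)
  expect_identical(rep$shared_multi, 1L)
  expect_identical(rep$membership$region[rep$membership$item == "chr1:10-11"],
                   "A&B")
})

test_that("category sharing adds shared and single counts", {
  # 30 timing genes: 17 in >= 2 comparisons, 13 in exactly one
  shared <- sprintf("s%02d", 1:17)
  single <- sprintf("u%02d", 1:13)
  sets <- list(A = c(shared, single[1:7]), B = c(shared, single[8:13]),
               C = shared[1:10])
  rep <- classify_parallelism(sets, level = "gene")
  cats <- tibble::tibble(gene = c(shared, single), category = "timing")
  out <- category_sharing(rep, cats)
  expect_identical(out$shared_multi, 17L)
  expect_identical(out$single, 13L)
  expect_identical(out$total, 30L)
})

test_that("directionality concordance uses the best significant site", {
  items <- tibble::tibble(item = c("g1", "g2", "g3"), chrom = "chr1",
                          start = c(100L, 500L, 900L),
                          end = c(200L, 600L, 1000L),
                          A = TRUE, B = c(TRUE, TRUE, FALSE))
  mk <- function(pos, std, sig) tibble::tibble(
    chrom = "chr1", pos = pos, std = std, significant = sig)
  xp <- list(
    A = mk(c(150L, 550L, 950L), c(2.5, 3.0, 2.0), c(TRUE, TRUE, TRUE)),
    B = mk(c(160L, 560L, 960L), c(1.9, -2.2, 9.9), c(TRUE, TRUE, FALSE))
  )
  out <- directionality_concordance(items, xp)
  expect_true(out$concordant[out$item == "g1"])    # both positive
  expect_false(out$concordant[out$item == "g2"])   # opposite signs
  expect_true(out$concordant[out$item == "g3"])    # only A shares it
  expect_equal(attr(out, "fraction"), 2 / 3)

  # undetermined: no significant site in a sharing comparison
  xp$B$significant <- c(FALSE, TRUE, FALSE)
  out2 <- directionality_concordance(items, xp)
  expect_false(out2$determined[out2$item == "g1"])
  expect_equal(attr(out2, "fraction"), 1 / 2)

  # no shared items: fraction undefined
  none <- items[0, ]
  out3 <- directionality_concordance(none, xp)
  expect_true(is.na(attr(out3, "fraction")))
})

test_that("functional categorization distinguishes genic, proximal and intergenic", {
  genes <- tibble::tibble(gene_id = "g1", chrom = "chr1",
                          start = 100000L, end = 110000L)
  items <- iv(105000, 105001,   # inside -> genic
              90000, 90001,     # 10 kb upstream -> proximal-regulatory
              300000, 300001)   # far -> intergenic
  out <- functional_categorize(items, genes)
  expect_identical(out$category,
                   c("genic", "proximal-regulatory", "intergenic"))

  set.seed(26)
  genes2 <- dplyr::mutate(random_intervals(5), gene_id = sprintf("g%d", 1:5))
  items2 <- random_intervals(30)
  got <- functional_categorize(items2, genes2, max_dist_bp = 50L)
  for (i in seq_len(nrow(items2))) {
    gaps <- vapply(seq_len(nrow(genes2)), function(j)
      oracle_gap(items2$start[i], items2$end[i],
                 genes2$start[j], genes2$end[j]), integer(1))
    ovl <- vapply(seq_len(nrow(genes2)), function(j)
      min(items2$end[i], genes2$end[j]) >
        max(items2$start[i], genes2$start[j]), logical(1))
    want <- if (any(ovl)) "genic"
            else if (any(gaps <= 50L)) "proximal-regulatory"
            else "intergenic"
    expect_identical(got$category[i], want)
  }
})
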