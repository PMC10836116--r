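test_that("extract_tags applies the cleavage-site convention", {
  aln <- data.table::data.table(
    chrom = "chr1", start = c(100L, 100L, 50L), end = c(140L, 140L, 90L),
    strand = c("+", "-", "+"), sample_id = "s1",
    unique = c(TRUE, TRUE, FALSE))
  tg <- extract_tags(aln)
  expect_equal(nrow(tg), 2L)                   # multimapper dropped
  expect_equal(tg$site, c(140L, 100L))         # + -> end, - -> start
  # flip-strand convention
  tgf <- extract_tags(aln, flip_strand = TRUE)
  expect_equal(tgf$strand, c("-", "+"))
  expect_equal(tgf$site, c(100L, 140L))
  # missing strand errors
  bad <- data.table::copy(aln)[1, strand := NA_character_]
  expect_error(extract_tags(bad), "strand")
})

test_that("cluster_sites implements inclusive 25-nt single linkage", {
  samples <- one_group_samples()
  mk <- function(sites, strand = "+") data.table::data.table(
    chrom = "chr1", strand = strand, site = as.integer(sites),
    sample_id = "ZT2_rep1")

  p <- cluster_sites(mk(c(100, 120, 146)), samples)
  expect_equal(p$info$start, c(100L, 146L))    # gap 26 splits, 20 chains
  expect_equal(p$info$end, c(120L, 146L))

  p25 <- cluster_sites(mk(c(100, 125)), samples)
  expect_equal(nrow(p25$info), 1L)             # distance 25 is inclusive

  # strands never merge
  both <- rbind(mk(500, "+"), mk(500, "-"))
  expect_equal(nrow(cluster_sites(both, samples)$info), 2L)

  # summit: max support, ties broken toward the 3' end
  tg <- rbind(mk(rep(100, 3)), mk(rep(110, 3)), mk(105))
  expect_equal(cluster_sites(tg, samples)$info$summit, 110L)
  tgm <- data.table::copy(tg)[, strand := "-"]
  expect_equal(cluster_sites(tgm, samples)$info$summit, 100L)

  # conservation: tags in == counts out
  set.seed(1)
  rnd <- mk(sample(1:2000, 400, replace = TRUE))
  rnd$sample_id <- sample(samples$sample_id, 400, replace = TRUE)
  pr <- cluster_sites(rnd, samples)
  expect_equal(sum(pr$counts), 400L)
})

test_that("cluster_sites matches a transitive-closure oracle", {
  skip_if_not_installed("igraph")
  samples <- one_group_samples()
  for (seed in 1:20) {
    set.seed(seed)
    n <- sample(20:200, 1)
    sites <- sort(sample(1:5000, n))
    tags <- data.table::data.table(chrom = "chr1", strand = "+",
                                   site = sites, sample_id = "ZT2_rep1")
    got <- cluster_sites(tags, samples)
    adj <- abs(outer(sites, sites, `-`)) <= 25
    g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
    comp <- igraph::components(g)$membership
    oracle_ranges <- t(vapply(split(sites, comp), range, numeric(2)))
    oracle_ranges <- oracle_ranges[order(oracle_ranges[, 1]), , drop = FALSE]
    expect_equal(got$info$start, unname(oracle_ranges[, 1]))
    expect_equal(got$info$end, unname(oracle_ranges[, 2]))
  }
})

test_that("filter_pacs applies the library-size-adaptive rule", {
  fp <- filter_params()
  small <- one_group_samples(lib = 1.0e6)
  large <- one_group_samples(lib = 2.0e6)
  mk_set <- function(counts, sheet = small) {
    colnames(counts) <- sheet$sample_id[seq_len(ncol(counts))]
    pac_set_from_counts(counts)
  }

  # (3,3,3,0,0), all < 1.7M -> retained
  expect_equal(nrow(filter_pacs(mk_set(matrix(c(3, 3, 3, 0, 0), 1)),
                                small, fp)$info), 1L)
  # (4,4,2,0,0), all < 1.7M -> only 2 samples >= 3 -> dropped
  expect_equal(nrow(filter_pacs(mk_set(matrix(c(4, 4, 2, 0, 0), 1)),
                                small, fp)$info), 0L)
  # (4,4,4,0,0), all > 1.7M -> retained
  expect_equal(nrow(filter_pacs(mk_set(matrix(c(4, 4, 4, 0, 0), 1)),
                                large, fp)$info), 1L)
  # same counts (3,3,3) fail under the large-library rule
  expect_equal(nrow(filter_pacs(mk_set(matrix(c(3, 3, 3, 0, 0), 1)),
                                large, fp)$info), 0L)
  # boundary: exactly 1.7M uses the stricter rule
  bdry <- one_group_samples(lib = 1700000)
  expect_equal(nrow(filter_pacs(mk_set(matrix(c(3, 3, 3, 0, 0), 1)),
                                bdry, fp)$info), 0L)

  # group with != 5 replicates warns but still applies the rule
  s4 <- small[1:4]
  expect_warning(filter_pacs(mk_set(matrix(c(3, 3, 3, 0), 1)), s4, fp),
                 "5 replicates")
})

test_that("filter is monotone: adding reads never drops a retained PAC", {
  set.seed(8)
  samples <- rbind(one_group_samples(lib = 1.1e6, condition = "ZT2"),
                   one_group_samples(lib = 2.0e6, condition = "ZT6"))
  for (rep_i in 1:50) {
    cnt <- matrix(rpois(10, 2), 1)
    colnames(cnt) <- samples$sample_id
    base_kept <- nrow(filter_pacs(pac_set_from_counts(cnt), samples)$info) == 1
    bumped <- cnt
    j <- sample(10, 1)
    bumped[1, j] <- bumped[1, j] + sample(1:3, 1)
    bump_kept <- nrow(filter_pacs(pac_set_from_counts(bumped),
                                  samples)$info) == 1
    if (base_kept) expect_true(bump_kept)
  }
})

test_that("mitochondrial removal and normalization behave as specified", {
  samples <- one_group_samples()
  cnt <- matrix(c(5, 0, 0, 0, 0,
                  10, 10, 10, 10, 10), 2, byrow = TRUE,
                dimnames = list(c("m", "k"), samples$sample_id))
  ps <- pac_set_from_counts(cnt)
  ps$info$chrom <- c("MT", "chr1")
  expect_equal(remove_mitochondrial(ps)$info$pac_id, "k")
  expect_equal(nrow(remove_mitochondrial(
    ps, filter_params(mito_chroms = character()))$info), 2L)

  # normalization arithmetic: count 5 of total 2.5e6 -> 20 per 1e7
  big <- matrix(c(5, 2.5e6 - 5), 2, 1,
                dimnames = list(c("a", "b"), "ZT2_rep1"))
  ps2 <- pac_set_from_counts(cbind(big, big, big, big, big))
  ps2$counts <- ps2$counts[, 1:5]
  colnames(ps2$counts) <- samples$sample_id
  nn <- normalize_pacs(ps2)
  expect_equal(nn$norm_counts["a", 1], 20)
  expect_equal(unname(colSums(nn$norm_counts)), rep(1e7, 5))

  # zero-total sample: warning, all-zero column
  cz <- matrix(c(1, 0), 1, 2,
               dimnames = list("a", c("s1", "s2")))
  psz <- pac_set_from_counts(cz)
  expect_warning(nz <- normalize_pacs(psz), "zero retained")
  expect_equal(unname(nz$norm_counts[1, ]), c(1e7, 0))
})

test_that("jitter-free synthetic tags recover planted PASs 1:1", {
  cfg <- sim_config(seed = 31, n_genes = 60, tag_jitter_sd_nt = 0,
                    base_mean_range = c(50, 200))
  sim <- simulate_genome(cfg)
  samples <- make_sample_sheet(cfg)
  cnt <- simulate_counts(cfg, samples, sim$truth)
  tags <- simulate_tags(cfg, sim$truth, cnt)
  pacs <- cluster_sites(tags, samples)
  expect_equal(nrow(pacs$info), nrow(sim$truth))
  expect_setequal(pacs$info$summit, sim$truth$coord)
  expect_true(all(pacs$info$start == pacs$info$end))
})
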