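test_that("VCF parsing keeps biallelic SNPs and skips the rest", {
  path <- tempfile(fileext = ".vcf")
  write_toy_vcf(c(
    toy_vcf_record(pos = 100),
    toy_vcf_record(pos = 200, ref = "AT", alt = "A"),   # indel
    toy_vcf_record(pos = 300, ref = "C", alt = "T")), path)
  v <- read_pooled_vcf(path, sim_sample_roles())
  expect_equal(nrow(v), 2L)
  expect_equal(v$pos, c(100, 300))
  expect_equal(unname(attr(v, "skipped")["non_biallelic_snp"]), 1L)

  # multiallelic records are dropped, not decomposed
  write_toy_vcf(c(toy_vcf_record(pos = 100),
                  toy_vcf_record(pos = 150, alt = "G,T",
                                 ads = c("0,40,5", "40,0,5", "5,40,0",
                                         "40,5,0"))), path)
  expect_equal(nrow(read_pooled_vcf(path, sim_sample_roles())), 1L)
})

test_that("sample columns are matched by name, not position", {
  p1 <- tempfile(fileext = ".vcf"); p2 <- tempfile(fileext = ".vcf")
  rec_ads <- c(EP02 = "0,45", EP01 = "45,0", ZS = "5,40", LS = "40,5")
  write_toy_vcf(toy_vcf_record(pos = 100, ads = unname(rec_ads)), p1)
  shuffle <- c("LS", "EP01", "ZS", "EP02")
  write_toy_vcf(toy_vcf_record(pos = 100, ads = unname(rec_ads[shuffle])),
                p2, samples = shuffle)
  v1 <- read_pooled_vcf(p1, sim_sample_roles())
  v2 <- read_pooled_vcf(p2, sim_sample_roles())
  attr(v1, "skipped") <- attr(v2, "skipped") <- NULL
  expect_identical(v1, v2)
  expect_equal(v1$bulk_green_ref, 40)
  expect_equal(v1$bulk_green_alt, 5)
})

test_that("AD fields are copied verbatim and missing roles/records error", {
  path <- tempfile(fileext = ".vcf")
  write_toy_vcf(toy_vcf_record(pos = 5, ads = c("0,45", "45,0", "5,40",
                                                "30,0")), path)
  v <- read_pooled_vcf(path, sim_sample_roles())
  expect_equal(v$bulk_green_ref, 30)
  expect_equal(v$bulk_green_alt, 0)
  expect_error(read_pooled_vcf(path, sim_sample_roles()[-1]),
               "sample_roles")
  expect_error(read_pooled_vcf(path, c(sim_sample_roles()[-1],
                                       parent_purple = "NOPE")),
               "not present")
})

test_that("unsorted input errors naming the offending record", {
  path <- tempfile(fileext = ".vcf")
  write_toy_vcf(c(toy_vcf_record(pos = 300), toy_vcf_record(pos = 100)),
                path)
  expect_error(read_pooled_vcf(path, sim_sample_roles()), "chr01:100")
})

test_that("records with missing AD are skipped and counted", {
  path <- tempfile(fileext = ".vcf")
  write_toy_vcf(c(toy_vcf_record(pos = 100),
                  toy_vcf_record(pos = 200, ads = c(".", "45,0", "5,40",
                                                    "40,5"))), path)
  v <- suppressMessages(read_pooled_vcf(path, sim_sample_roles()))
  expect_equal(nrow(v), 1L)
  expect_equal(unname(attr(v, "skipped")["missing_ad"]), 1L)
})

test_that("quality filters enforce the documented bounds", {
  # below the depth floor -> excluded under the DP rule
  low_dp <- make_variant(pos = 1, dp = 50)
  res <- apply_quality_filters(low_dp)
  expect_equal(nrow(res$retained), 0L)
  expect_equal(unname(res$removed_counts["dp"]), 1L)

  # exact boundary values all pass (inclusive bounds)
  boundary <- make_variant(pos = 2, dp = 60, qual = 50, mq = 50, qd = 2,
                           fs = 40, an = 5, sor = 5)
  expect_equal(nrow(apply_quality_filters(boundary)$retained), 1L)
  upper <- make_variant(pos = 3, dp = 1000)
  expect_equal(nrow(apply_quality_filters(upper)$retained), 1L)
})

test_that("each excluded record is attributed to its first violated rule", {
  vs <- make_variants(
    make_variant(pos = 1, dp = 10),                 # dp
    make_variant(pos = 2, dp = 2000, qual = 10),    # dp (first in order)
    make_variant(pos = 3, qual = 10),               # qual
    make_variant(pos = 4, mq = 20),                 # mq
    make_variant(pos = 5, qd = 1),                  # qd
    make_variant(pos = 6, fs = 90),                 # fs
    make_variant(pos = 7, an = 2),                  # an
    make_variant(pos = 8),                          # clean
    make_variant(pos = 9, sor = 9),                 # sor
    make_variant(pos = 10),                         # clean
    make_variant(pos = 11))                         # clean
  res <- apply_quality_filters(vs)
  expect_equal(nrow(res$retained), 3L)
  expect_equal(res$retained$pos, c(8, 10, 11))
  expect_equal(sum(res$removed_counts), 8L)
  expect_equal(unname(res$removed_counts[c("dp", "qual", "mq", "qd", "fs",
                                           "an", "sor")]),
               c(2L, 1L, 1L, 1L, 1L, 1L, 1L))
})

test_that("a missing QC metric fails its rule", {
  v <- make_variant(pos = 1, qd = NA)
  res <- apply_quality_filters(v)
  expect_equal(nrow(res$retained), 0L)
  expect_equal(unname(res$removed_counts["qd"]), 1L)
})

test_that("filtering is idempotent and partitions the input", {
  set.seed(11)
  vs <- do.call(rbind, lapply(1:60, function(i)
    make_variant(pos = i * 10, dp = sample(c(30, 180, 1200), 1),
                 qual = sample(c(20, 900), 1), fs = sample(c(1, 50), 1))))
  res1 <- apply_quality_filters(vs)
  res2 <- apply_quality_filters(res1$retained)
  expect_identical(res1$retained, res2$retained)
  expect_equal(sum(res2$removed_counts), 0L)
  expect_equal(nrow(res1$retained) + sum(res1$removed_counts), nrow(vs))
})

test_that("parent-informativeness keeps oppositely fixed parents only", {
  vs <- make_variants(
    make_variant(pos = 1, parent_purple = c(0, 40), parent_green = c(38, 0)),
    make_variant(pos = 2, parent_purple = c(20, 20), parent_green = c(0, 40)),
    make_variant(pos = 3, parent_purple = c(1, 39), parent_green = c(39, 1)),
    make_variant(pos = 4, parent_purple = c(0, 40), parent_green = c(0, 38)),
    make_variant(pos = 5, parent_purple = c(0, 4), parent_green = c(4, 0)))
  out <- select_informative_snps(vs, min_parent_depth = 10, tolerance = 0.05)
  # kept: opposite fixation (1) and minor fraction 0.025 <= 0.05 (3);
  # removed: heterozygous parent (2), same-allele parents (4), depth < 10 (5)
  expect_equal(out$pos, c(1, 3))
})

test_that("output is (chrom, pos) sorted with strictly increasing positions", {
  sim <- simulate_bsa_experiment(genome = genome_spec(n_chrom = 3),
                                 qtl = qtl_spec(chrom = "chr02"),
                                 n = 250, seed = 4)
  path <- tempfile(fileext = ".vcf")
  write_sim_vcf(sim$variants, path)
  v <- read_pooled_vcf(path, sim_sample_roles())
  expect_false(is.unsorted(order(v$chrom, v$pos)))
  for (ch in unique(v$chrom))
    expect_true(all(diff(v$pos[v$chrom == ch]) > 0))
})
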