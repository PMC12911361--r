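test_that("asv_table validates identifiers and counts", {
  m <- matrix(1:6, 2, 3, dimnames = list(c("s1", "s2"), c("a", "b", "c")))
  t1 <- asv_table(m, "16S")
  expect_s3_class(t1, "asv_table")
  expect_identical(attr(t1, "marker"), "16S")

  dup <- m; rownames(dup) <- c("s1", "s1")
  expect_error(asv_table(dup, "16S"), "s1")
  dup2 <- m; colnames(dup2) <- c("a", "a", "c")
  expect_error(asv_table(dup2, "16S"), "a")
  neg <- m; neg[2, 3] <- -1
  expect_error(asv_table(neg, "16S"), "\\[s2, c\\]")
})

test_that("read_asv_table parses, validates, and auto-orients", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\ta1\ta2",
               "s1\t3\t0", "s2\t1\t5", "s3\t2\t2"), f)
  t1 <- read_asv_table(f, "18S")
  expect_equal(dim(t1), c(3L, 2L))
  expect_equal(unclass(t1)["s2", "a2"], 5, ignore_attr = TRUE)

  fdup <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\ta1", "s1\t3", "s1\t1"), fdup)
  expect_error(read_asv_table(fdup, "16S"), "duplicate sample id: s1")

  fempty <- withr::local_tempfile(fileext = ".tsv")
  writeLines("sample_id\ta1", fempty)
  expect_error(read_asv_table(fempty, "16S"), "no samples")

  # ASVs-as-rows layout is transposed back to samples-as-rows
  fwide <- withr::local_tempfile(fileext = ".tsv")
  asv_rows <- c("asv\ts1\ts2",
                paste0("a", 1:7, "\t", 1:7, "\t", 7:1))
  writeLines(asv_rows, fwide)
  t2 <- read_asv_table(fwide, "16S")
  expect_equal(rownames(t2), c("s1", "s2"))
  expect_equal(ncol(t2), 7L)
})

test_that("rarefy draws without replacement to the exact depth", {
  m <- rbind(s1 = c(10, 0), s2 = c(6, 4), s3 = c(2, 1))
  colnames(m) <- c("a", "b")
  tab <- asv_table(m, "16S")

  suppressMessages(r <- rarefy(tab, depth = 5, seed = 1))
  expect_true(all(rowSums(r) == 5))
  expect_equal(unclass(r)["s1", ], c(a = 5, b = 0))   # single-taxon sample
  expect_identical(attr(r, "dropped_samples"), "s3")

  # a sample whose total equals the depth is returned unchanged
  r2 <- rarefy(asv_table(rbind(s1 = c(a = 3, b = 2)), "16S"), depth = 5, seed = 1)
  expect_equal(unclass(r2)["s1", ], c(a = 3, b = 2))

  expect_error(rarefy(tab, depth = 1000, seed = 1), "exceeds every sample")

  # support preservation: absent taxa stay absent
  big <- asv_table(random_counts(5, 8, seed = 2), "16S")
  zeroed <- unclass(big) == 0
  rb <- rarefy(big, depth = min(rowSums(big)), seed = 3)
  expect_true(all(unclass(rb)[zeroed[rownames(rb), ]] == 0))
})

test_that("rarefaction matches the hypergeometric expectation", {
  tab <- asv_table(rbind(s1 = c(a = 6, b = 4)), "16S")
  draws <- vapply(1:2000, function(s)
    unclass(rarefy(tab, depth = 5, seed = s))[1, 1], numeric(1))
  # mean of first coordinate is 5 * 6/10 = 3 (multivariate hypergeometric)
  expect_equal(mean(draws), 3.0, tolerance = 0.03)
})

test_that("relative_abundance normalises rows and rejects empty samples", {
  expect_equal(relative_abundance(rbind(s = c(5, 5)))[1, ], c(0.5, 0.5))
  expect_equal(relative_abundance(rbind(s = c(10, 0)))[1, ], c(1, 0))
  expect_error(relative_abundance(rbind(s = c(0, 0))), "zero-total")
  for (seed in 1:3) {
    ra <- relative_abundance(random_counts(6, 10, seed) + 1)
    expect_equal(unname(rowSums(ra)), rep(1, 6), tolerance = 1e-12)
  }
})

test_that("assign_groups maps lineages to phytoplankton groups", {
  tax <- data.frame(
    asv_id = paste0("a", 1:6),
    lineage = c(
      "Eukaryota;Stramenopiles;Ochrophyta;Pelagophyceae;Pelagomonas",
      "Bacteria;Cyanobacteria;Cyanobiaceae;Prochlorococcus;Prochlorococcus MIT9301",
      "Eukaryota;Opisthokonta;Metazoa;Copepoda",
      "Eukaryota;Stramenopiles;Ochrophyta;Phaeophyceae",   # non-photo class
      "Eukaryota;Alveolata;Dinoflagellata;Dinophyceae;Gymnodinium",
      "Eukaryota;Archaeplastida;Chlorophyta;Mamiellophyceae"),
    stringsAsFactors = FALSE)
  g <- assign_groups(tax)
  expect_equal(unname(g), c("Stramenopiles_photosynthetic", "Prochlorococcus",
                            "Other", "Other", "Dinoflagellata",
                            "Archaeplastida"))
  expect_warning(g2 <- assign_groups(tax, asv_ids = c("a1", "zz")), "missing")
  expect_equal(unname(g2["zz"]), "Other")
})

test_that("classify_persistence follows the three-cruise detection rule", {
  mk <- function(a, b, c) asv_table(rbind(s1 = c(x = a, y = b, z = c),
                                          s2 = c(x = a, y = 0, z = c)), "16S")
  tabs <- list(`2016` = mk(3, 1, 0), `2017` = mk(2, 0, 0), `2019` = mk(1, 4, 0))
  expect_warning(lab <- classify_persistence(tabs), "absent in all years")
  expect_equal(lab$label[lab$asv_id == "x"], "persistent")
  expect_equal(lab$label[lab$asv_id == "y"], "ephemeral")
  expect_equal(lab$years[lab$asv_id == "y"], "2016,2019")
  expect_false("z" %in% lab$asv_id)

  expect_error(classify_persistence(tabs[1:2]), "three")

  # invariant to sample order and within-year duplication
  dup <- tabs
  dupm <- unclass(tabs[["2016"]])[c(2, 1, 1), ]
  rownames(dupm) <- c("s2", "s1", "s1b")
  dup[["2016"]] <- asv_table(dupm, "16S")
  expect_warning(lab2 <- classify_persistence(dup), "absent")
  expect_equal(lab2[order(lab2$asv_id), c("asv_id", "label")],
               lab[order(lab$asv_id), c("asv_id", "label")],
               ignore_attr = TRUE)
})

test_that("assign_region applies the salinity and chlorophyll fronts", {
  meta <- data.frame(salinity = c(35.1, 34.0, 34.0),
                     chlorophyll = c(0.05, 0.30, 0.10))
  expect_equal(assign_region(meta), c("NPSG", "NTZ", "STZ"))

  # complete hydrography: every sample lands in exactly one region
  set.seed(1)
  meta2 <- data.frame(salinity = runif(50, 33.5, 35.5),
                      chlorophyll = runif(50, 0.01, 0.5))
  expect_true(all(assign_region(meta2) %in% c("NPSG", "STZ", "NTZ")))

  # front-latitude fallback when hydrography is missing
  meta3 <- data.frame(salinity = NA_real_, chlorophyll = NA_real_,
                      latitude = c(30, 33, 37), year = 2016)
  fronts <- data.frame(year = 2016, salinity_front_lat = 32.3,
                       chl_front_lat = 35)
  expect_equal(assign_region(meta3, front_latitudes = fronts),
               c("NPSG", "STZ", "NTZ"))
  expect_warning(assign_region(meta3), "unassigned")
})

test_that("depth_bin matches the survey depth categories", {
  expect_equal(as.character(depth_bin(c(0, 15, 60, 110))),
               c("0-15", "0-15", "45-75", "90-125"))
})
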