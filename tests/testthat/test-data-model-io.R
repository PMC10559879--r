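test_that("default design enumerates 12 distinct replicates with paired samples", {
  d <- default_design()
  reps <- unique(d[c("run", "replicate")])
  expect_equal(nrow(reps), 12L)
  expect_false(anyDuplicated(paste(d$mix_id, d$channel_id)) > 0)
  # every redoxome sample appears once per label stage in its mix
  rx <- d[d$layer == "redoxome", ]
  per_sample <- table(paste(rx$mix_id, rx$replicate, rx$timepoint,
                            rx$treatment))
  expect_true(all(per_sample == 2))
})

test_that("design reader validates and round-trips", {
  d <- default_design()
  path <- withr::local_tempfile(fileext = ".tsv")
  write_design(d, path)
  d2 <- read_design(path)
  expect_equal(d2$mix_id, d$mix_id)
  expect_equal(d2$replicate_global, d$replicate_global)

  empty <- withr::local_tempfile(fileext = ".tsv")
  writeLines(paste(c("layer", "mix_id", "channel_id", "run", "replicate",
                     "timepoint", "treatment", "label_stage"),
                   collapse = "\t"), empty)
  expect_error(read_design(empty), "no design rows")
})

test_that("design invariant violations are rejected with located messages", {
  d <- default_design()
  dup <- rbind(d, d[1, ])
  expect_error(validate_design(dup), "duplicate \\(mix_id, channel_id\\)")

  # drop one TMT2 twin from a redox mix
  rx_row <- which(d$layer == "redoxome" & d$label_stage == "TMT2")[1]
  broken <- d[-rx_row, ]
  expect_error(validate_design(broken), "TMT1/TMT2 twin")

  bad <- d
  bad$treatment[1] <- "dosed"
  expect_error(validate_design(bad), "unknown treatment")

  bad2 <- d
  bad2$layer[1] <- "metabolome"
  expect_error(validate_design(bad2), "unknown layer")
})

test_that("peptide table reader parses sites and treats blanks as missing", {
  design <- tiny_design()
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "mix_id\tprotein_accession\tpeptide_sequence\tsites\tch01\tch02\tch03\tch04",
    "redox_r01_4h\tP1\tACDK\tC152;C156\t100\t50\t2\t3",
    "redox_r01_4h\tP2\tMCNK\tC10\t\t7\t1\t4"), path)
  x <- read_peptide_table(path, design, layer = "redoxome")
  expect_equal(nrow(x), 2L)
  expect_equal(strsplit(x$sites[1], ";")[[1]], c("C152", "C156"))
  expect_true(is.na(x$ch01[2]))
  expect_false(is.na(x$ch02[2]))
})

test_that("peptide table reader rejects invalid rows with locations", {
  design <- tiny_design()
  bad_site <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "mix_id\tprotein_accession\tpeptide_sequence\tsites\tch01\tch02\tch03\tch04",
    "redox_r01_4h\tP1\tACDK\tX10\t1\t2\t3\t4"), bad_site)
  expect_error(read_peptide_table(bad_site, design, layer = "redoxome"),
               "row 1.*X10")

  neg <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "mix_id\tprotein_accession\tpeptide_sequence\tsites\tch01\tch02\tch03\tch04",
    "redox_r01_4h\tP1\tACDK\tC10\t-1\t2\t3\t4"), neg)
  expect_error(read_peptide_table(neg, design, layer = "redoxome"),
               "negative intensity")

  orphan <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c(
    "mix_id\tprotein_accession\tpeptide_sequence\tsites\tch01\tch99",
    "prot_r01\tP1\tACDK\t\t1\t2"), orphan)
  expect_error(read_peptide_table(orphan, design, layer = "proteome"),
               "no design entry")
})

test_that("site id parsing accepts valid ids and rejects others", {
  s <- parse_site_id(c("C105", "S536", "Y9"))
  expect_equal(s$residue, c("C", "S", "Y"))
  expect_equal(s$position, c(105L, 536L, 9L))
  expect_error(parse_site_id("X10"), "unparseable")
  expect_error(parse_site_id("C"), "unparseable")
  expect_equal(format_site_id("C", 105), "C105")
})

test_that("result tables round-trip through write/read within 1e-9", {
  df <- data.frame(entity = c("P1", "P2"), layer = "proteome",
                   timepoint = "4h", n = c(12L, 3L),
                   log2fc_mean = c(0.123456789012345, -2.5e-7),
                   p = c(0.02, NA), fdr = c(0.04, NA),
                   significant = c(TRUE, FALSE), stringsAsFactors = FALSE)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_table(df, path)
  back <- read_table(path)
  expect_equal(names(back), names(df))
  expect_equal(back$log2fc_mean, df$log2fc_mean, tolerance = 1e-9)
  expect_true(is.na(back$p[2]))

  empty <- df[0, ]
  path2 <- withr::local_tempfile(fileext = ".tsv")
  write_table(empty, path2)
  expect_equal(length(readLines(path2)), 1L) # header only
})

test_that("GMT and mapping files round-trip", {
  gs <- gene_set_collection("toy", list(A = c("G1", "G2"), B = c("G2", "G3")))
  path <- withr::local_tempfile(fileext = ".gmt")
  write_gmt(gs, path)
  back <- read_gmt(path)
  expect_equal(back$sets, gs$sets)
  expect_error(gene_set_collection("bad", list(A = character(0))),
               "non-empty")

  mp <- c(P1 = "G1", P2 = "G2")
  mpath <- withr::local_tempfile(fileext = ".tsv")
  write_mapping(mp, mpath)
  expect_equal(read_mapping(mpath), mp)
})

test_that("annotation reader enforces partner rules", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_accession\tsite\tannotation\tpartner",
               "P10599\tC32\tdisulfide_partner\tC35",
               "P04406\tC152\tknown_modified\t"), path)
  ann <- read_site_annotations(path)
  expect_equal(nrow(ann), 2L)

  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_accession\tsite\tannotation\tpartner",
               "P10599\tC32\tdisulfide_partner\t"), bad)
  expect_error(read_site_annotations(bad), "must carry a partner")

  bad2 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("protein_accession\tsite\tannotation\tpartner",
               "P10599\tZ9\tknown_modified\t"), bad2)
  expect_error(read_site_annotations(bad2), "unparseable")
})
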