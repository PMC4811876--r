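fixture <- grasfam_example("gras_table1.tsv")

test_that("the bundled curated table parses into one locus per row with split segments", {
  tab <- read_locus_table(fixture)
  expect_equal(dplyr::n_distinct(tab$locus_id), 52L)
  scr1 <- tab[tab$locus_id == "Vitvi08g00007", ]
  expect_equal(nrow(scr1), 2L)
  expect_equal(scr1$start, c(115793, 116647))
  expect_equal(scr1$end, c(116261, 117596))
  expect_equal(unique(scr1$strand), "-")
  expect_equal(unique(scr1$chromosome), 8L)
})

test_that("a header-only table yields zero loci, not an error", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines("locus_id\tshort_name\tstrand\tposition", path)
  expect_equal(nrow(read_locus_table(path)), 0L)
})

test_that("en dash and hyphen span separators are both accepted", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("locus_id\tshort_name\tstrand\tposition",
               "Vitvi08g00007\tSCR1\t-\t115793–116261, 116647–117596"),
             path)
  tab <- read_locus_table(path)
  expect_equal(tab$start, c(115793, 116647))
})

test_that("malformed spans and duplicate locus IDs are rejected with the row named", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("locus_id\tshort_name\tstrand\tposition",
               "Vitvi01g00001\tBAD1\t+\t200-100"), path)
  expect_error(read_locus_table(path), "Vitvi01g00001")
  writeLines(c("locus_id\tshort_name\tstrand\tposition",
               "Vitvi01g00001\tBAD1\t+\t1-abc"), path)
  expect_error(read_locus_table(path), "malformed span")
  writeLines(c("locus_id\tshort_name\tstrand\tposition",
               "Vitvi01g00001\tA\t+\t1-9",
               "Vitvi01g00001\tB\t+\t20-29"), path)
  expect_error(read_locus_table(path), "duplicate locus_id")
})

test_that("parse -> write -> parse is the identity on the fixture", {
  tab <- read_locus_table(fixture)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_locus_table(tab, path)
  expect_equal(read_locus_table(path), tab)
})

test_that("every fixture locus satisfies the table invariants as shipped", {
  tab <- read_locus_table(fixture)
  expect_identical(validate_locus_table(tab), tab)
  expect_true(all(tab$end >= tab$start))
  expect_true(all(tab$exon >= 1L))
})

test_that("equivalent GFF3 and locus-table encodings give the same loci", {
  tab_txt <- c("locus_id\tshort_name\tstrand\tposition",
               "Vitvi08g00007\tSCR1\t-\t115793-116261, 116647-117596",
               "Vitvi02g00974\tSCL3b\t+\t13518884-13519177")
  tsv <- withr::local_tempfile(fileext = ".tsv")
  writeLines(tab_txt, tsv)
  from_table <- read_locus_table(tsv)

  gff <- withr::local_tempfile(fileext = ".gff3")
  write_family_gff3(from_table, gff)
  from_gff <- read_family_gff3(gff)
  expect_equal(from_gff, from_table)
})

test_that("minus-strand GFF3 genes keep segments in ascending genomic order", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr8\ttest\tgene\t100\t900\t.\t-\t.\tID=Vitvi08g00010;Name=G1",
               "chr8\ttest\texon\t500\t900\t.\t-\t.\tID=e2;Parent=Vitvi08g00010",
               "chr8\ttest\texon\t100\t200\t.\t-\t.\tID=e1;Parent=Vitvi08g00010"),
             gff)
  tab <- read_family_gff3(gff)
  expect_equal(tab$start, c(100, 500))
  expect_equal(unique(tab$strand), "-")
  expect_equal(exon_count(tab, "Vitvi08g00010"), 2L)
})

test_that("a GFF3 exon without a gene parent is an error", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr8\ttest\tgene\t100\t900\t.\t+\t.\tID=g1",
               "chr8\ttest\texon\t100\t200\t.\t+\t.\tID=e1;Parent=unknown"),
             gff)
  expect_error(read_family_gff3(gff), "Parent")
})

test_that("FASTA reading preserves order, uppercases, and X-substitutes with warning", {
  path <- withr::local_tempfile(fileext = ".faa")
  writeLines(c(">p1 some description", "mkrDELLA", ">p2", "ACDEF"), path)
  recs <- read_protein_fasta(path)
  expect_equal(recs$id, c("p1", "p2"))
  expect_equal(recs$sequence[1L], "MKRDELLA")

  writeLines(c(">p1", "AC1EF"), path)
  expect_warning(recs <- read_protein_fasta(path), "replaced by X")
  expect_equal(recs$sequence, "ACXEF")

  writeLines(character(0), path)
  expect_error(read_protein_fasta(path), "no FASTA records")
})

test_that("generator FASTA round-trips byte-identically through write and read", {
  cfg <- simulation_config(seed = 7L, n_subfamilies = 10L,
                           members_per_subfamily = 3L,
                           protein_length = c(320L, 380L),
                           n_tandem_arrays = 0L, n_segmental_pairs = 0L,
                           module_size = 5L)
  sim <- simulate_family(cfg)
  expect_equal(nrow(sim$genome1), 30L)
  p1 <- withr::local_tempfile(fileext = ".faa")
  p2 <- withr::local_tempfile(fileext = ".faa")
  write_protein_fasta(sim$genome1, p1)
  back <- read_protein_fasta(p1)
  expect_equal(back$id, sim$genome1$id)
  expect_equal(back$sequence, sim$genome1$sequence)
  write_protein_fasta(back, p2)
  expect_identical(readBin(p1, "raw", file.size(p1)),
                   readBin(p2, "raw", file.size(p2)))
})

test_that("segment maps validate interval orientation and round-trip", {
  map <- tibble::tibble(chrom_a = 1L, start_a = 100, end_a = 900,
                        chrom_b = 14L, start_b = 5000, end_b = 9000)
  path <- withr::local_tempfile(fileext = ".tsv")
  write_segment_map(map, path)
  expect_equal(read_segment_map(path), map)
  bad <- map
  bad$end_b <- 10
  expect_error(validate_segment_map(bad), "end < start")
})
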