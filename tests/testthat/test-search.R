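# Shared synthetic database built once per file.
db_layouts <- list(c(H = 8, L = 3, E = 5), c(E = 6, L = 2, H = 4),
                   c(H = 12, L = 4), c(L = 5, E = 7, L = 3),
                   c(E = 4, L = 2, E = 6, H = 5))
make_db_traces <- function(seeds = 1:5, layouts = db_layouts) {
  lapply(seq_along(seeds), function(i) {
    tr <- make_trace(fixture_spec(seed = seeds[i],
                                  layout = layouts[[(i - 1) %% length(layouts) + 1]]))
    tr$structure_id <- sprintf("chain%02d", i)
    tr
  })
}

test_that("qualification is an inclusive ratio threshold", {
  expect_true(qualifies(2.5, 2.5, 0.2))
  expect_false(qualifies(0, 2.5, 0.2))
  expect_true(qualifies(0.5, 2.5, 0.2))    # exactly at threshold
  expect_false(qualifies(0.49, 2.5, 0.2))
  expect_error(qualifies(1, 0, 0.2), "degenerate query")
})

test_that("build_database parses a directory and sorts by chain length", {
  dir <- withr::local_tempdir()
  traces <- make_db_traces()
  for (tr in traces)
    write_pdb(tr, file.path(dir, paste0(tr$structure_id, ".pdb")))
  db <- build_database(dir)
  expect_length(db, 5L)
  lens <- vapply(db$records, function(r) length(r$desc), integer(1))
  expect_true(all(diff(lens) >= 0))
  # rebuild after adding a file picks up the new chain
  extra <- make_trace(fixture_spec(seed = 99, layout = c(H = 5, L = 2)))
  extra$structure_id <- "extra"
  write_pdb(extra, file.path(dir, "extra.pdb"))
  expect_length(build_database(dir), 6L)
  expect_error(build_database(withr::local_tempdir()), "empty database")
})

test_that("the binary cache round-trips field by field", {
  dir <- withr::local_tempdir()
  db <- database_from_traces(make_db_traces())
  path <- file.path(dir, "cache.bin")
  write_database(db, path)
  got <- load_database(path)
  expect_identical(length(got), length(db))
  for (k in seq_along(db$records)) {
    a <- db$records[[k]]; b <- got$records[[k]]
    expect_identical(a$id, b$id)
    expect_identical(a$reduced$sse, b$reduced$sse)
    expect_identical(a$reduced$lengths, b$reduced$lengths)
    expect_equal(a$desc$c_len, b$desc$c_len, tolerance = 1e-12)
    expect_equal(a$desc$gamma, b$desc$gamma, tolerance = 1e-12)
    expect_identical(a$desc$sse, b$desc$sse)
    expect_identical(a$desc$residues, b$desc$residues)
    expect_equal(a$trace$coords, b$trace$coords, tolerance = 1e-12)
    expect_identical(a$trace$seq_ids, b$trace$seq_ids)
  }
})

test_that("stale or truncated caches are rejected", {
  dir <- withr::local_tempdir()
  db <- database_from_traces(make_db_traces(1:2))
  path <- file.path(dir, "cache.bin")
  write_database(db, path)
  bytes <- readBin(path, "raw", file.size(path))
  bad <- file.path(dir, "bad.bin")
  writeBin(head(bytes, length(bytes) - 40L), bad)
  expect_error(load_database(bad), "truncated")
  bytes2 <- bytes
  bytes2[6] <- as.raw(9)     # version field follows the 5 magic bytes
  writeBin(bytes2, bad)
  expect_error(load_database(bad), "stale cache")
  writeBin(charToRaw("NOTADATABASE"), bad)
  expect_error(load_database(bad), "not a structure database")
})

test_that("an exact copy of the query ranks first with ratio 1", {
  query <- make_trace(fixture_spec(seed = 50, layout = c(H = 7, L = 3, E = 6)))
  copy <- query; copy$structure_id <- "copy"
  db <- database_from_traces(c(make_db_traces(), list(copy)))
  hits <- search_structures(query, db, search_params(q_t = 0.2))
  expect_identical(hits$db_id[hits$rank == 1 & !is.na(hits$rank)], "copy")
  expect_equal(hits$ratio[hits$db_id == "copy"], 1)
})

test_that("q_t = 0 turns the filter off; q_t = 1 on dissimilar chains empties it", {
  query <- make_trace(fixture_spec(seed = 51, layout = c(H = 9, E = 4, L = 3)))
  db <- database_from_traces(make_db_traces())
  all_in <- search_structures(query, db, search_params(q_t = 0))
  expect_true(all(all_in$qualified))
  expect_true(all(!is.na(all_in$phase2_score)))
  none <- search_structures(query, db, search_params(q_t = 1))
  expect_false(any(none$qualified))
  expect_true(all(is.na(none$rank)))
})

test_that("raising q_t only shrinks the qualified set", {
  query <- make_trace(fixture_spec(seed = 52, layout = c(H = 6, L = 2, E = 5)))
  db <- database_from_traces(make_db_traces(1:10,
    rep(db_layouts, 2)))
  qsets <- lapply(c(0.01, 0.3, 0.6, 0.9), function(qt) {
    h <- search_structures(query, db, search_params(q_t = qt))
    sort(h$db_id[h$qualified])
  })
  for (k in 2:length(qsets))
    expect_true(all(qsets[[k]] %in% qsets[[k - 1]]))
})

test_that("results are independent of database record order", {
  withr::local_seed(53)
  query <- make_trace(fixture_spec(seed = 54, layout = c(E = 5, L = 3, H = 8)))
  db <- database_from_traces(make_db_traces())
  h1 <- search_structures(query, db, search_params(q_t = 0.1))
  db2 <- db; db2$records <- db2$records[sample(length(db2$records))]
  h2 <- search_structures(query, db2, search_params(q_t = 0.1))
  o1 <- h1[order(h1$db_id), ]; o2 <- h2[order(h2$db_id), ]
  expect_equal(o1$phase1_score, o2$phase1_score, tolerance = 1e-12)
  expect_equal(o1$phase2_score, o2$phase2_score, tolerance = 1e-12)
  expect_identical(o1$rank, o2$rank)
})

test_that("a rigid-motion copy is recovered end to end", {
  withr::local_seed(55)
  query <- make_trace(fixture_spec(seed = 56, layout = c(H = 8, L = 4, E = 6)))
  copy <- query
  copy$structure_id <- "moved_copy"
  R <- random_rotation()
  copy$coords <- t(R %*% t(copy$coords)) +
    matrix(c(11, -7, 3), length(copy), 3, byrow = TRUE)
  db <- database_from_traces(c(make_db_traces(), list(copy)))
  hits <- search_structures(query, db, search_params(q_t = 0.2))
  expect_identical(hits$db_id[1], "moved_copy")
  expect_identical(hits$rank[1], 1L)
  expect_equal(hits$ratio[1], 1)
  aln <- alignment_report(hits, db, rank = 1)
  expect_lte(aln$superposition$rmsd, 1e-6)
  expect_identical(aln$superposition$n_pairs, length(query))
})

test_that("the rendered report shows identities, gaps and the score", {
  query <- make_trace(fixture_spec(seed = 57, layout = c(H = 6, E = 5)))
  copy <- query; copy$structure_id <- "copy"
  db <- database_from_traces(c(make_db_traces(1:2), list(copy)))
  hits <- search_structures(query, db, search_params(q_t = 0.2))
  aln <- alignment_report(hits, db, db_id = "copy")
  txt <- aln$text
  match_line <- txt[grep("^Query  ", txt) + 1L]
  expect_true(all(grepl("^ +\\|+$", match_line)))
  score_line <- grep("^Score:", txt, value = TRUE)
  printed <- as.numeric(sub("^Score: ([0-9.]+).*", "\\1", score_line))
  expect_equal(printed, aln$phase2_score, tolerance = 1e-4)
  # a planted deletion shows as a gap character
  d <- build_descriptor_chain(query)
  keep <- setdiff(seq_len(length(d)), 5L)
  cut <- new_descriptor_chain("cut", d$c_len[keep], d$gamma[keep],
                              d$sse[keep], d$residues[keep])
  p <- phase2_align(d, cut)
  lines <- render_alignment(p, d, cut)
  expect_true(any(grepl("-", lines[grep("^Target ", lines)], fixed = TRUE)))
})

test_that("superposed coordinates can be written back as PDB", {
  dir <- withr::local_tempdir()
  query <- make_trace(fixture_spec(seed = 58, layout = c(H = 7, E = 6)))
  copy <- query; copy$structure_id <- "copy"
  copy$coords <- copy$coords + matrix(c(5, 5, 5), length(copy), 3, byrow = TRUE)
  db <- database_from_traces(c(make_db_traces(1:2), list(copy)))
  hits <- search_structures(query, db, search_params(q_t = 0.2))
  aln <- alignment_report(hits, db, db_id = "copy")
  out <- file.path(dir, "sup.pdb")
  write_superposed(aln, db, out)
  moved <- parse_structure(readLines(out), "A")
  expect_equal(moved$coords, query$coords, tolerance = 1e-3)
})

test_that("the command-line interface builds a cache and runs a search", {
  skip_on_os("windows")
  dir <- withr::local_tempdir()
  pdbdir <- file.path(dir, "pdb"); dir.create(pdbdir)
  traces <- make_db_traces(1:3)
  for (tr in traces)
    write_pdb(tr, file.path(pdbdir, paste0(tr$structure_id, ".pdb")))
  qfile <- file.path(dir, "query.pdb")
  write_pdb(traces[[1]], qfile)
  cli <- system.file("scripts", "foldscan.R", package = "foldscan")
  rscript <- file.path(R.home("bin"), "Rscript")
  cache <- file.path(dir, "cache.bin")
  r1 <- system2(rscript, c(cli, "build-db", pdbdir, "-o", cache),
                stdout = TRUE, stderr = TRUE)
  expect_true(file.exists(cache))
  json <- file.path(dir, "hits.json")
  r2 <- system2(rscript, c(cli, "search", qfile, "--chain", "A",
                           "--db", cache, "--qt", "0.2", "--json", json),
                stdout = TRUE, stderr = TRUE)
  expect_identical(attr(r2, "status"), NULL)   # exit 0
  expect_true(file.exists(json))
  top <- jsonlite::read_json(json, simplifyVector = TRUE)
  expect_identical(top$db_id[1], "chain01_A")
  expect_equal(top$ratio[1], 1)
})
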