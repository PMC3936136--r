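#' Search parameters
#'
#' Tunables of the filter-and-refine scan: the qualification threshold
#' `q_t` in `[0, 1]` (a database chain enters phase 2 when its phase-1
#' score is at least `q_t` times the query self-score; `q_t = 0` turns
#' the filter off and every chain passes), the number `top_m` of
#' top-ranked hits eligible for residue-level backtracking and
#' superposition, the per-phase gap penalties and the phase-2 component
#' weights.
#'
#' @param q_t qualification threshold in `[0, 1]`.
#' @param top_m positive count of reported top hits.
#' @param gaps1,gaps2 [gap_penalties()] for phases 1 and 2.
#' @param weights [phase2_weights()].
#' @return An object of class `search_params`.
#' @export
search_params <- function(q_t = 0.2, top_m = 10L,
                          gaps1 = gap_penalties(1.0, 0.1),
                          gaps2 = gap_penalties(2.0, 0.2),
                          weights = phase2_weights()) {
  if (q_t < 0 || q_t > 1) stop("q_t must lie in [0, 1]")
  top_m <- as.integer(top_m)
  if (top_m < 1L) stop("top_m must be positive")
  stopifnot(inherits(gaps1, "gap_penalties"), inherits(gaps2, "gap_penalties"),
            inherits(weights, "phase2_weights"))
  structure(list(q_t = q_t, top_m = top_m, gaps1 = gaps1, gaps2 = gaps2,
                 weights = weights),
            class = "search_params")
}

#' Qualification test for phase 2
#'
#' A database chain qualifies for high-resolution alignment when
#' `score_qd / score_qq >= q_t` (inclusive), where `score_qq` is the
#' query's phase-1 self-score.
#'
#' @param score_qd phase-1 score of the database chain against the query.
#' @param score_qq positive phase-1 self-score of the query.
#' @param q_t qualification threshold in `[0, 1]`.
#' @return Logical.
#' @export
qualifies <- function(score_qd, score_qq, q_t) {
  if (any(score_qq <= 0)) stop("degenerate query: self-score is zero")
  score_qd / score_qq >= q_t
}

.DB_MAGIC <- "FSCDB"
.DB_VERSION <- 1L
.DB_BLOCK <- 32L
.SSE_CODE <- c(H = 1L, E = 2L, L = 3L)

# One database record: everything the three phases need for one chain.
.make_record <- function(trace) {
  desc <- build_descriptor_chain(trace)
  list(id = trace$structure_id, trace = trace, desc = desc,
       reduced = reduce_chain(desc))
}

#' Build a searchable structure database from a directory of PDB files
#'
#' Parses every chain of every `.pdb`/`.ent` file in `pdb_dir`, builds
#' its descriptor and reduced chains, and assembles the cache with
#' records sorted ascending by residue count (record ids are
#' `<file>_<chain>`). Chains that fail to parse are skipped with a
#' message. When `out` is given the cache is also serialised to a
#' binary file for fast reloading with [load_database()].
#'
#' @param pdb_dir directory of PDB files.
#' @param out optional path for the binary cache.
#' @return An object of class `structure_db`.
#' @export
build_database <- function(pdb_dir, out = NULL) {
  files <- list.files(pdb_dir, pattern = "\\.(pdb|ent)$", full.names = TRUE)
  records <- list()
  for (f in files) {
    txt <- readLines(f, warn = FALSE)
    base <- sub("\\.[^.]*$", "", basename(f))
    chains <- tryCatch({
      pdb <- .read_pdb_object(txt)
      a <- pdb$atom[pdb$atom$type == "ATOM" & pdb$atom$elety == "CA", ]
      unique(a$chain[!is.na(a$chain)])
    }, error = function(e) character(0))
    for (ch in chains) {
      rec <- tryCatch({
        tr <- parse_structure(txt, ch, structure_id = paste(base, ch, sep = "_"))
        .make_record(assign_sse(txt, tr))
      }, error = function(e) {
        message("skipping ", base, " chain ", ch, ": ", conditionMessage(e))
        NULL
      })
      if (!is.null(rec)) records[[length(records) + 1L]] <- rec
    }
  }
  if (length(records) == 0L) stop("empty database: no parseable chains")
  lens <- vapply(records, function(r) length(r$desc), integer(1))
  db <- structure(list(version = .DB_VERSION, block_size = .DB_BLOCK,
                       records = records[order(lens)]),
                  class = "structure_db")
  if (!is.null(out)) write_database(db, out)
  db
}

#' Assemble a database from in-memory traces
#'
#' Companion of [build_database()] for traces already in memory (e.g.
#' synthetic ones from [make_trace()]).
#'
#' @param traces list of [calpha_trace] objects with unique ids.
#' @return A `structure_db`.
#' @export
database_from_traces <- function(traces) {
  stopifnot(length(traces) >= 1L)
  records <- lapply(traces, .make_record)
  lens <- vapply(records, function(r) length(r$desc), integer(1))
  structure(list(version = .DB_VERSION, block_size = .DB_BLOCK,
                 records = records[order(lens)]),
            class = "structure_db")
}

#' @export
print.structure_db <- function(x, ...) {
  lens <- vapply(x$records, function(r) length(r$desc), integer(1))
  cat(sprintf("<structure_db> %d chains, %d-%d residues (cache v%d, block %d)\n",
              length(x$records), min(lens), max(lens), x$version, x$block_size))
  invisible(x)
}

#' @export
length.structure_db <- function(x) length(x$records)

.write_chr <- function(con, s) {
  r <- charToRaw(enc2utf8(s))
  writeBin(length(r), con, size = 4L)
  writeBin(r, con)
}
.read_chr <- function(con) {
  n <- readBin(con, "integer", 1L, size = 4L)
  if (length(n) != 1L) stop("truncated cache file")
  rawToChar(readBin(con, "raw", n))
}
.read_checked <- function(con, what, n, size = NA_integer_) {
  x <- readBin(con, what, n, size = size)
  if (length(x) != n) stop("truncated cache file")
  x
}

#' Serialise a structure database to a binary cache
#'
#' Format: magic bytes, a version byte, the block size (chains per
#' subpackage, metadata describing how records would be grouped for
#' batched processing), the chain count, then length-prefixed per-chain
#' records (id, reduced chain, descriptor chain, Calpha coordinates and
#' residue numbering), in ascending length order. The cache must be
#' rebuilt when the database contents change.
#'
#' @param db a `structure_db`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_database <- function(db, path) {
  stopifnot(inherits(db, "structure_db"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(charToRaw(.DB_MAGIC), con)
  writeBin(c(db$version, db$block_size, length(db$records)), con, size = 4L)
  for (r in db$records) {
    .write_chr(con, r$id)
    red <- r$reduced
    writeBin(length(red$sse), con, size = 4L)
    writeBin(unname(.SSE_CODE[red$sse]), con, size = 4L)
    writeBin(red$lengths, con, size = 4L)
    d <- r$desc
    writeBin(length(d), con, size = 4L)
    writeBin(d$c_len, con)
    writeBin(d$gamma, con)
    writeBin(unname(.SSE_CODE[d$sse]), con, size = 4L)
    .write_chr(con, paste(d$residues, collapse = ""))
    writeBin(r$trace$seq_ids, con, size = 4L)
    writeBin(as.vector(r$trace$coords), con)
    .write_chr(con, r$trace$chain_id)
  }
  invisible(path)
}

#' Load a binary structure database cache
#'
#' Inverse of [write_database()]. A version mismatch signals a stale
#' cache that must be rebuilt; a truncated file signals a decode error.
#'
#' @param path cache file from [write_database()]/[build_database()].
#' @return A `structure_db` identical to the one written.
#' @export
load_database <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- rawToChar(.read_checked(con, "raw", nchar(.DB_MAGIC)))
  if (magic != .DB_MAGIC) stop("not a structure database cache")
  version <- .read_checked(con, "integer", 1L, size = 4L)
  if (version != .DB_VERSION)
    stop("stale cache, rebuild required (version ", version, ")")
  block <- .read_checked(con, "integer", 1L, size = 4L)
  n <- .read_checked(con, "integer", 1L, size = 4L)
  sse_names <- names(.SSE_CODE)
  records <- vector("list", n)
  for (k in seq_len(n)) {
    id <- .read_chr(con)
    nr <- .read_checked(con, "integer", 1L, size = 4L)
    rsse <- sse_names[.read_checked(con, "integer", nr, size = 4L)]
    rlen <- .read_checked(con, "integer", nr, size = 4L)
    q <- .read_checked(con, "integer", 1L, size = 4L)
    c_len <- .read_checked(con, "double", q)
    gamma <- .read_checked(con, "double", q)
    sse <- sse_names[.read_checked(con, "integer", q, size = 4L)]
    residues <- strsplit(.read_chr(con), "")[[1]]
    seq_ids <- .read_checked(con, "integer", q, size = 4L)
    coords <- matrix(.read_checked(con, "double", 3L * q), q, 3L)
    chain_id <- .read_chr(con)
    trace <- new_calpha_trace(id, chain_id, coords, residues, sse, seq_ids)
    records[[k]] <- list(id = id, trace = trace,
                         desc = new_descriptor_chain(id, c_len, gamma,
                                                     sse, residues),
                         reduced = new_reduced_chain(id, rsse, rlen))
  }
  structure(list(version = version, block_size = block, records = records),
            class = "structure_db")
}

#' Scan a structure database for chains similar to a query
#'
#' The full filter-and-refine pipeline: the query's reduced chain is
#' scored by phase 1 against every database chain (via the query
#' profile); chains whose score reaches `q_t` times the query phase-1
#' self-score qualify; qualified chains are re-scored by phase 2 at
#' residue level and ranked by that score (ties by id). Unqualified
#' chains are reported after the ranking with their phase-1 evidence
#' only. Use [alignment_report()] on a ranked hit for the residue-level
#' path, superposition and printable alignment.
#'
#' @param query a [calpha_trace] (with secondary structure assigned).
#' @param db a `structure_db`.
#' @param params a [search_params()] object.
#' @return A data frame of class `foldscan_hits` with one row per
#'   database chain: `db_id`, `phase1_score`, `ratio`, `qualified`,
#'   `phase2_score` (`NA` for unqualified chains) and `rank` (`NA` for
#'   unranked chains). Attributes carry the query, its self-score and
#'   the parameters.
#' @export
search_structures <- function(query, db, params = search_params()) {
  stopifnot(inherits(query, "calpha_trace"), inherits(db, "structure_db"),
            inherits(params, "search_params"))
  qdesc <- build_descriptor_chain(query)
  qred <- reduce_chain(qdesc)
  profile <- build_phase1_profile(qred)
  score_qq <- phase1_self_score(qred, gaps = params$gaps1)
  if (score_qq <= 0 && params$q_t > 0)
    stop("degenerate query: phase-1 self-score is zero; ",
         "set q_t = 0 to scan the whole database without the filter")
  s1 <- vapply(db$records,
               function(r) phase1_score(profile, r$reduced,
                                        gaps = params$gaps1)$score,
               numeric(1))
  ratio <- if (score_qq > 0) s1 / score_qq else rep(NA_real_, length(s1))
  qual <- if (params$q_t == 0) rep(TRUE, length(s1))
          else qualifies(s1, score_qq, params$q_t)
  s2 <- rep(NA_real_, length(s1))
  s2[qual] <- vapply(db$records[qual],
                     function(r) phase2_score(qdesc, r$desc,
                                              gaps = params$gaps2,
                                              w = params$weights)$score,
                     numeric(1))
  ids <- vapply(db$records, `[[`, character(1), "id")
  hits <- data.frame(db_id = ids, phase1_score = s1, ratio = ratio,
                     qualified = qual, phase2_score = s2,
                     rank = NA_integer_, stringsAsFactors = FALSE)
  ord_q <- order(-hits$phase2_score[qual], hits$db_id[qual])
  ranked <- which(qual)[ord_q]
  hits$rank[ranked] <- seq_along(ranked)
  rest <- setdiff(seq_len(nrow(hits)), ranked)
  hits <- hits[c(ranked, rest[order(-hits$ratio[rest], hits$db_id[rest])]), ]
  rownames(hits) <- NULL
  attr(hits, "params") <- params
  attr(hits, "query") <- query
  attr(hits, "query_desc") <- qdesc
  attr(hits, "score_qq") <- score_qq
  class(hits) <- c("foldscan_hits", class(hits))
  hits
}

#' @export
print.foldscan_hits <- function(x, n = attr(x, "params")$top_m, ...) {
  p <- attr(x, "params")
  cat(sprintf("Structure search: %d chains scanned, %d qualified (q_t = %g)\n",
              nrow(x), sum(x$qualified), p$q_t))
  cat(sprintf("Query phase-1 self-score: %.3f\n", attr(x, "score_qq")))
  top <- x[!is.na(x$rank) & x$rank <= n, , drop = FALSE]
  if (nrow(top) == 0L) cat("No qualified hits.\n")
  else print.data.frame(top, digits = 4, row.names = FALSE)
  invisible(x)
}

#' Residue-level report for one ranked hit
#'
#' Recomputes the phase-2 alignment of a ranked hit with the full
#' similarity matrix, backtracks the residue-level path, superposes the
#' aligned Calpha pairs (Kabsch) and renders a printable alignment.
#'
#' @param hits a `foldscan_hits` result from [search_structures()].
#' @param db the `structure_db` that was searched.
#' @param rank rank of the hit to report (default 1); alternatively give
#'   `db_id`.
#' @param db_id id of the hit to report (overrides `rank`).
#' @return An object of class `foldscan_alignment`: list with `db_id`,
#'   `path`, `superposition`, `phase2_score`, `ratio` and `text` (the
#'   rendered report lines).
#' @export
alignment_report <- function(hits, db, rank = 1L, db_id = NULL) {
  stopifnot(inherits(hits, "foldscan_hits"), inherits(db, "structure_db"))
  row <- if (!is.null(db_id)) hits[hits$db_id == db_id, , drop = FALSE]
         else hits[!is.na(hits$rank) & hits$rank == rank, , drop = FALSE]
  if (nrow(row) != 1L || !row$qualified)
    stop("no such ranked hit")
  params <- attr(hits, "params")
  qdesc <- attr(hits, "query_desc")
  rec <- db$records[[match(row$db_id, vapply(db$records, `[[`,
                                             character(1), "id"))]]
  path <- phase2_align(qdesc, rec$desc, gaps = params$gaps2,
                       w = params$weights)
  sup <- tryCatch(rmsd_of_path(path, attr(hits, "query"), rec$trace),
                  error = function(e) NULL)
  txt <- render_alignment(path, qdesc, rec$desc,
                          score = attr(path, "score"), ratio = row$ratio,
                          sup = sup)
  structure(list(db_id = row$db_id, path = path, superposition = sup,
                 phase2_score = attr(path, "score"), ratio = row$ratio,
                 text = txt),
            class = "foldscan_alignment")
}

#' @export
print.foldscan_alignment <- function(x, ...) {
  cat(x$text, sep = "\n")
  invisible(x)
}

#' Render a residue-level alignment as text
#'
#' Block-formatted local alignment: query residue line, match line
#' (`|` identity, `:` positive structural agreement, space otherwise),
#' database residue line and both SSE lines, preceded by the similarity
#' measures.
#'
#' @param path an `alignment_path`.
#' @param query_desc,db_desc the aligned
#'   [descriptor_chain][new_descriptor_chain] objects.
#' @param score phase-2 score to print (defaults to the path score).
#' @param ratio phase-1 qualification ratio to print, if known.
#' @param sup optional `superposition_result` for the RMSD line.
#' @param width residues per block.
#' @return Character vector of report lines.
#' @export
render_alignment <- function(path, query_desc, db_desc,
                             score = attr(path, "score"), ratio = NA,
                             sup = NULL, width = 60L) {
  qc <- ifelse(is.na(path$q), "-", query_desc$residues[path$q])
  dc <- ifelse(is.na(path$d), "-", db_desc$residues[path$d])
  qs <- ifelse(is.na(path$q), "-", query_desc$sse[path$q])
  ds <- ifelse(is.na(path$d), "-", db_desc$sse[path$d])
  match_ch <- ifelse(!is.na(path$q) & !is.na(path$d) & qc == dc, "|",
                     ifelse(!is.na(path$q) & !is.na(path$d) & qs == ds,
                            ":", " "))
  head <- c(sprintf("Query: %s (%d residues)  Target: %s (%d residues)",
                    query_desc$id, length(query_desc),
                    db_desc$id, length(db_desc)),
            sprintf("Score: %.4f  Ratio: %s  Aligned: %d",
                    score, ifelse(is.na(ratio), "-", sprintf("%.3f", ratio)),
                    sum(!is.na(path$q) & !is.na(path$d))))
  if (!is.null(sup))
    head <- c(head, sprintf("RMSD: %.4f A over %d CA pairs",
                            sup$rmsd, sup$n_pairs))
  blocks <- character(0)
  n <- nrow(path)
  if (n > 0L) for (s in seq(1L, n, by = width)) {
    e <- min(s + width - 1L, n)
    idx <- s:e
    blocks <- c(blocks, "",
                paste0("Q SSE  ", paste(qs[idx], collapse = "")),
                paste0("Query  ", paste(qc[idx], collapse = "")),
                paste0("       ", paste(match_ch[idx], collapse = "")),
                paste0("Target ", paste(dc[idx], collapse = "")),
                paste0("T SSE  ", paste(ds[idx], collapse = "")))
  }
  c(head, blocks)
}

#' Write the superposed mobile structure as a PDB file
#'
#' Applies the superposition of an [alignment_report()] to the full
#' database chain and writes it (Calpha only) for external viewers.
#'
#' @param aln a `foldscan_alignment`.
#' @param db the searched `structure_db`.
#' @param path output PDB path.
#' @return `path`, invisibly.
#' @export
write_superposed <- function(aln, db, path) {
  stopifnot(inherits(aln, "foldscan_alignment"))
  if (is.null(aln$superposition)) stop("no superposition available")
  rec <- db$records[[match(aln$db_id, vapply(db$records, `[[`,
                                             character(1), "id"))]]
  tr <- rec$trace
  tr$coords <- apply_superposition(aln$superposition, tr$coords)
  write_pdb(tr, path)
  invisible(path)
}
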