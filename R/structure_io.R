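#' @title Calpha traces read from PDB files
#' @description A `calpha_trace` holds one protein chain as an ordered
#' Calpha backbone: coordinates in Angstrom, one-letter residue codes,
#' per-residue secondary-structure labels and the author residue numbers.
#' @name calpha_trace
NULL

#' Construct a Calpha trace
#'
#' Low-level constructor; [parse_structure()] and [read_structure()] are
#' the usual entry points.
#'
#' @param structure_id character scalar identifying the structure.
#' @param chain_id one-character chain identifier.
#' @param coords numeric q x 3 matrix of Calpha coordinates (Angstrom).
#' @param residues character vector of one-letter amino-acid codes.
#' @param sse character vector of secondary-structure codes, each one of
#'   `"H"` (alpha-helix), `"E"` (beta-strand/sheet) or `"L"` (loop, turn,
#'   coil or undetermined).
#' @param seq_ids integer vector of author residue numbers.
#' @param n_skipped number of residues dropped for lacking a Calpha atom.
#' @return An object of class `calpha_trace`.
#' @export
new_calpha_trace <- function(structure_id, chain_id, coords, residues,
                             sse = NULL, seq_ids = NULL, n_skipped = 0L) {
  coords <- as.matrix(coords)
  if (is.null(dim(coords)) || ncol(coords) != 3L)
    stop("coords must be a q x 3 matrix")
  q <- nrow(coords)
  if (q < 1L) stop("empty trace")
  if (!all(is.finite(coords))) stop("non-finite coordinates")
  if (is.null(sse)) sse <- rep("L", q)
  if (is.null(seq_ids)) seq_ids <- seq_len(q)
  residues <- as.character(residues)
  sse <- as.character(sse)
  seq_ids <- as.integer(seq_ids)
  if (length(residues) != q || length(sse) != q || length(seq_ids) != q)
    stop("coords, residues, sse and seq_ids must have identical length")
  if (!all(sse %in% c("H", "E", "L")))
    stop("sse codes must be H, E or L")
  structure(
    list(structure_id = as.character(structure_id)[1],
         chain_id = as.character(chain_id)[1],
         coords = unname(coords), residues = residues, sse = sse,
         seq_ids = seq_ids, n_skipped = as.integer(n_skipped)),
    class = "calpha_trace")
}

#' @export
print.calpha_trace <- function(x, ...) {
  cat(sprintf("<calpha_trace> %s chain %s: %d residues (%d skipped, no CA)\n",
              x$structure_id, x$chain_id, length(x$residues), x$n_skipped))
  cat("  sse: ", paste(rle(x$sse)$values,
                       rle(x$sse)$lengths, sep = "", collapse = " "), "\n")
  invisible(x)
}

#' @export
length.calpha_trace <- function(x) length(x$residues)

# Drop HELIX/SHEET lines whose residue-number columns do not parse;
# bio3d aborts on them, the format says to skip them.
.sanitize_header <- function(lines) {
  ok_int <- function(s) grepl("^\\s*-?\\d+\\s*$", s)
  is_helix <- startsWith(lines, "HELIX")
  is_sheet <- startsWith(lines, "SHEET")
  bad <- logical(length(lines))
  bad[is_helix] <- !(ok_int(substring(lines[is_helix], 22, 25)) &
                       ok_int(substring(lines[is_helix], 34, 37)))
  bad[is_sheet] <- !(ok_int(substring(lines[is_sheet], 23, 26)) &
                       ok_int(substring(lines[is_sheet], 34, 37)))
  if (any(bad))
    warning("ignoring ", sum(bad), " malformed HELIX/SHEET record(s)")
  lines[!bad]
}

# Parse PDB text through bio3d; returns the bio3d pdb object.
.read_pdb_object <- function(pdb_text) {
  lines <- unlist(strsplit(pdb_text, "\n", fixed = TRUE), use.names = FALSE)
  lines <- .sanitize_header(lines)
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf))
  writeLines(lines, tf)
  suppressWarnings(bio3d::read.pdb(tf, multi = FALSE, verbose = FALSE))
}

#' Parse a PDB chain into a Calpha trace
#'
#' Extracts the Calpha backbone of one chain from PDB text: one entry per
#' residue possessing a CA atom, in file order. Residues without a CA atom
#' are skipped and counted in `n_skipped`. For alternate locations the
#' first-listed conformer is kept; non-standard residues map to code
#' `"X"`. Only the first NMR model is read. Secondary structure is
#' initialised to all-`"L"`; use [assign_sse()] to label it.
#'
#' @param pdb_text character vector of PDB lines (or a single string with
#'   embedded newlines).
#' @param chain_id one-character chain identifier.
#' @param structure_id optional identifier stored on the trace.
#' @return A [calpha_trace].
#' @export
parse_structure <- function(pdb_text, chain_id, structure_id = "structure") {
  pdb <- .read_pdb_object(pdb_text)
  atoms <- pdb$atom[pdb$atom$type == "ATOM", , drop = FALSE]
  atoms <- atoms[!is.na(atoms$chain) & atoms$chain == chain_id, , drop = FALSE]
  if (nrow(atoms) == 0L) stop("chain not found: ", chain_id)
  ins <- ifelse(is.na(atoms$insert), "", atoms$insert)
  rkey <- paste(atoms$resno, ins, sep = "|")
  ca <- atoms[atoms$elety == "CA", , drop = FALSE]
  if (nrow(ca) == 0L) stop("empty trace: chain ", chain_id, " has no CA atoms")
  ca_ins <- ifelse(is.na(ca$insert), "", ca$insert)
  ca_key <- paste(ca$resno, ca_ins, sep = "|")
  ca <- ca[!duplicated(ca_key), , drop = FALSE]   # first-listed altloc wins
  n_skipped <- length(setdiff(unique(rkey), unique(ca_key)))
  res1 <- suppressWarnings(bio3d::aa321(ca$resid))
  res1[is.na(res1) | !(res1 %in% .AA20)] <- "X"
  new_calpha_trace(structure_id = structure_id, chain_id = chain_id,
                   coords = cbind(ca$x, ca$y, ca$z),
                   residues = res1, seq_ids = ca$resno,
                   n_skipped = n_skipped)
}

.AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "V", "W", "Y")

# Residue numbers covered by HELIX or SHEET records on one chain.
.record_cover <- function(rec, chain_id) {
  if (is.null(rec) || length(rec$start) == 0L) return(integer(0))
  start <- suppressWarnings(as.integer(rec$start))
  end <- suppressWarnings(as.integer(rec$end))
  chain <- rec$chain
  bad <- is.na(start) | is.na(end) | end < start
  if (any(bad)) {
    warning("ignoring ", sum(bad), " malformed HELIX/SHEET record(s)")
    start <- start[!bad]; end <- end[!bad]; chain <- chain[!bad]
  }
  keep <- !is.na(chain) & chain == chain_id
  if (!any(keep)) return(integer(0))
  unlist(Map(seq.int, start[keep], end[keep]), use.names = FALSE)
}

#' Assign secondary structure from HELIX/SHEET records
#'
#' Labels each trace residue from the PDB header: residues covered by a
#' HELIX record (any helix class) become `"H"`, residues covered by a
#' SHEET record become `"E"`, everything else stays `"L"`. Overlaps
#' resolve in favour of HELIX. Malformed records are ignored with a
#' warning.
#'
#' @param pdb_text the same PDB text the trace was parsed from.
#' @param trace a [calpha_trace] from [parse_structure()].
#' @return The trace with its `sse` field filled in; length unchanged.
#' @export
assign_sse <- function(pdb_text, trace) {
  stopifnot(inherits(trace, "calpha_trace"))
  pdb <- .read_pdb_object(pdb_text)
  helix <- .record_cover(pdb$helix, trace$chain_id)
  sheet <- .record_cover(pdb$sheet, trace$chain_id)
  sse <- rep("L", length(trace$residues))
  sse[trace$seq_ids %in% sheet] <- "E"
  sse[trace$seq_ids %in% helix] <- "H"   # HELIX wins on overlap
  trace$sse <- sse
  trace
}

#' Read one chain of a PDB file
#'
#' Convenience wrapper: [parse_structure()] followed by [assign_sse()].
#'
#' @param path path to a PDB file.
#' @param chain_id one-character chain identifier.
#' @param structure_id identifier stored on the trace; defaults to the
#'   file name without extension.
#' @return A [calpha_trace] with secondary structure assigned.
#' @export
read_structure <- function(path, chain_id,
                           structure_id = sub("\\.[^.]*$", "", basename(path))) {
  txt <- readLines(path, warn = FALSE)
  tr <- parse_structure(txt, chain_id, structure_id = structure_id)
  assign_sse(txt, tr)
}
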