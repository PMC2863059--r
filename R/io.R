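#' Read protein sequences from FASTA
#'
#' @param path Path to a FASTA file.
#' @param strict If `TRUE` (default) any character outside the 20-letter
#'   amino-acid alphabet is a validation error naming the record and position.
#' @return A named list of [protein_record] objects (names are the FASTA ids,
#'   taken as the first whitespace-delimited token of each header).
#' @export
read_fasta <- function(path, strict = TRUE) {
  if (!file.exists(path)) fr_stop("file not found: ", path)
  set <- tryCatch(Biostrings::readBStringSet(path),
                  error = function(e) fr_stop("malformed FASTA '", path, "': ",
                                              conditionMessage(e)))
  if (length(set) == 0L) fr_stop("FASTA file '", path, "' contains no records")
  ids <- vapply(strsplit(names(set), "\\s+"), `[`, character(1), 1L)
  recs <- lapply(seq_along(set), function(k) {
    protein_record(ids[k], as.character(set[[k]]), strict = strict)
  })
  names(recs) <- ids
  recs
}

#' Read a 3-state secondary-structure string
#'
#' The file holds a single line over `{H, E, C}` (helix, strand, coil), one
#' character per residue.
#'
#' @param path Path to the SS file.
#' @return The SS string (validated, upper-cased).
#' @export
read_ss <- function(path) {
  if (!file.exists(path)) fr_stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) != 1L)
    fr_stop("SS file '", path, "' must contain exactly one non-empty line")
  ss <- toupper(trimws(lines[1]))
  validate_ss(ss, id = basename(path))
  ss
}

#' Read a contact probability map (CASP-RR-style text)
#'
#' The dialect: optional header lines whose first non-blank character is not a
#' digit, then data lines `i j p` (whitespace-separated, 1-based residue
#' indices, `i < j`, probability in `[0, 1]`). Unlisted pairs have probability
#' zero; symmetry is enforced by mirroring.
#'
#' @param path Path to the contact file.
#' @param n Residue count (map dimension).
#' @return A [contact_map] of dimension `n`.
#' @export
read_contact_map <- function(path, n) {
  if (!file.exists(path)) fr_stop("file not found: ", path)
  n <- as.integer(n)
  if (is.na(n) || n < 1L) fr_stop("'n' must be a positive residue count")
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  data <- lines[grepl("^[0-9]", lines)]
  if (!length(data)) return(contact_map(matrix(numeric(0), ncol = 3), n = n))
  fields <- strsplit(data, "\\s+")
  bad <- which(lengths(fields) < 3L)
  if (length(bad))
    fr_stop(sprintf("contact file '%s': line '%s' does not have 3 fields",
                    path, data[bad[1]]))
  trip <- t(vapply(fields, function(f) as.numeric(f[1:3]), numeric(3)))
  if (any(!is.finite(trip)))
    fr_stop("contact file '", path, "': unparseable numeric field")
  i <- trip[, 1]; j <- trip[, 2]; p <- trip[, 3]
  if (any(i >= j))
    fr_stop("contact file '", path, "': indices must satisfy i < j")
  if (any(j > n))
    fr_stop(sprintf("contact file '%s': residue index %d exceeds n = %d",
                    path, max(j), n))
  if (any(p < 0 | p > 1))
    fr_stop("contact file '", path, "': probability outside [0, 1]")
  contact_map(trip, n = n)
}

#' Write a contact probability map
#'
#' Emits the same dialect [read_contact_map] consumes: one `i j p` line per
#' non-zero unordered pair, `i < j`, probability printed with 6 decimals.
#' Reading the result back reproduces the map bit-exactly at that precision.
#'
#' @param map A [contact_map].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_contact_map <- function(map, path) {
  stopifnot(is_contact_map(map))
  m <- unclass(map)
  idx <- which(upper.tri(m) & m > 0, arr.ind = TRUE)
  idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
  lines <- sprintf("%d %d %.6f", idx[, 1], idx[, 2], m[idx])
  writeLines(lines, path)
  invisible(path)
}

#' Read the experimental rate dataset table
#'
#' Tab-separated, header `id log_rate kinetic_label` with optional `gc_value`
#' column. Labels are normalized case-insensitively ("Two-State" ->
#' `"two_state"`). Rates are log10(k_f / sec^-1).
#'
#' @param path Path to the TSV file.
#' @return A data.frame with columns `id`, `log_rate`, `kinetic_label` and,
#'   when present in the file, `gc_value`.
#' @export
read_rate_table <- function(path) {
  if (!file.exists(path)) fr_stop("file not found: ", path)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character")
  need <- c("id", "log_rate", "kinetic_label")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    fr_stop("rate table '", path, "' lacks column(s): ",
            paste(miss, collapse = ", "))
  if (anyDuplicated(tab$id))
    fr_stop("rate table '", path, "': duplicate id '",
            tab$id[duplicated(tab$id)][1], "'")
  rate <- suppressWarnings(as.numeric(tab$log_rate))
  if (any(is.na(rate)))
    fr_stop(sprintf("rate table '%s': unparseable log_rate in row %d",
                    path, which(is.na(rate))[1]))
  out <- data.frame(
    id = tab$id,
    log_rate = rate,
    kinetic_label = vapply(seq_len(nrow(tab)), function(k) {
      normalize_kinetic_label(tab$kinetic_label[k],
                              context = sprintf("row %d", k))
    }, character(1)),
    stringsAsFactors = FALSE
  )
  if ("gc_value" %in% names(tab)) {
    gc <- suppressWarnings(as.numeric(tab$gc_value))
    bad <- which(is.na(gc) & nzchar(trimws(tab$gc_value)))
    if (length(bad))
      fr_stop(sprintf("rate table '%s': unparseable gc_value in row %d",
                      path, bad[1]))
    out$gc_value <- gc
  }
  out
}

#' Write a rate dataset table
#'
#' @param tab A data.frame as returned by [read_rate_table].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rate_table <- function(tab, path) {
  cols <- c("id", "log_rate", "kinetic_label",
            intersect("gc_value", names(tab)))
  utils::write.table(tab[, cols], path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Load a full dataset of protein records from a directory
#'
#' Convenience loader for the on-disk layout the synthetic generator (and the
#' CLI) use: `rates.tsv`, `sequences.fasta`, and per-protein `<id>.rr`,
#' `<id>.ss` and optional `<id>.pdb` files.
#'
#' @param dir Dataset directory.
#' @param strict Passed to [read_fasta].
#' @return A named list of [protein_record]s with maps, SS strings, rates and
#'   labels attached (and C-alpha coordinates where a PDB file is present).
#' @export
read_benchmark <- function(dir, strict = TRUE) {
  tab <- read_rate_table(file.path(dir, "rates.tsv"))
  seqs <- read_fasta(file.path(dir, "sequences.fasta"), strict = strict)
  miss <- setdiff(tab$id, names(seqs))
  if (length(miss))
    fr_stop("ids in rates.tsv missing from FASTA: ", paste(miss, collapse = ", "))
  recs <- lapply(seq_len(nrow(tab)), function(k) {
    id <- tab$id[k]
    L <- nchar(seqs[[id]]$sequence)
    pdb <- file.path(dir, paste0(id, ".pdb"))
    protein_record(
      id, seqs[[id]]$sequence,
      ss_string = read_ss(file.path(dir, paste0(id, ".ss"))),
      map = read_contact_map(file.path(dir, paste0(id, ".rr")), n = L),
      ca_coords = if (file.exists(pdb)) read_pdb_ca(pdb, chain = "A", n = L),
      log_rate = tab$log_rate[k],
      kinetic_label = tab$kinetic_label[k],
      gc_value = if (!is.null(tab$gc_value)) tab$gc_value[k],
      strict = strict
    )
  })
  names(recs) <- tab$id
  recs
}
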