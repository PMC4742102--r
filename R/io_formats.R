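#' Read a plate-level measurement table
#'
#' Parses a delimited (TSV, or CSV detected by sniffing) table of per-well
#' luminescence readings. Required columns: `plate`, `well`, `role`, `id`,
#' `signal`. Well addresses are accepted either as letter-number strings
#' ("A01", "P24") or as `row:col` integer pairs and are stored canonically as
#' 1-based `(well_row, well_col)` integers.
#'
#' @param path Path to the table.
#' @return A `data.table` with columns `plate`, `well_row`, `well_col`,
#'   `role`, `id`, `signal`, one row per well.
#' @details Roles must come from the closed vocabulary
#'   `library`, `non_transfected`, `negative_control`, `positive_control`,
#'   `dmso`, `bortezomib`. Unknown roles, non-numeric or negative signals,
#'   and duplicated `(plate, well)` addresses are hard errors naming the
#'   offending row. A header-only file yields an empty table with a warning.
#' @export
read_plate_table <- function(path) {
  dt <- .read_delim(path)
  need <- c("plate", "well", "role", "id", "signal")
  miss <- setdiff(need, names(dt))
  if (length(miss)) {
    stop("plate table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  if (nrow(dt) == 0L) {
    warning("plate table ", path, " has a header but no rows")
    return(data.table(plate = character(), well_row = integer(),
                      well_col = integer(), role = character(),
                      id = character(), signal = numeric()))
  }
  bad_role <- which(!dt$role %in% ROLE_LEVELS)
  if (length(bad_role)) {
    stop("unknown role '", dt$role[bad_role[1]], "' in row ", bad_role[1],
         " of ", path)
  }
  sig <- suppressWarnings(as.numeric(dt$signal))
  bad_sig <- which(is.na(sig) & !is.na(dt$signal))
  if (length(bad_sig)) {
    stop("non-numeric signal '", dt$signal[bad_sig[1]], "' in row ",
         bad_sig[1], " of ", path)
  }
  if (any(sig < 0, na.rm = TRUE)) {
    stop("negative signal in row ", which(sig < 0)[1], " of ", path)
  }
  rc <- parse_well(as.character(dt$well))
  out <- data.table(plate = as.character(dt$plate),
                    well_row = rc$row, well_col = rc$col,
                    role = as.character(dt$role),
                    id = as.character(dt$id),
                    signal = sig)
  dup <- duplicated(out[, c("plate", "well_row", "well_col")])
  if (any(dup)) {
    stop("duplicated (plate, well) address in row ", which(dup)[1],
         " of ", path)
  }
  out[]
}

#' Write a plate-level measurement table
#'
#' Inverse of [read_plate_table()]; wells are written back as "A01"-style
#' addresses. Deterministic: identical input always yields byte-identical
#' files.
#'
#' @param wells Table as returned by [read_plate_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_plate_table <- function(wells, path) {
  out <- data.table(plate = wells$plate,
                    well = format_well(wells$well_row, wells$well_col),
                    role = wells$role, id = wells$id,
                    signal = sprintf("%.6f", wells$signal))
  fwrite(out, path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Read an siRNA library annotation table
#'
#' Required columns: `sirna_id`, `gene`, `guide_sequence`. Guide sequences
#' are upper-cased and DNA-style T is mapped to U so downstream seed matching
#' is alphabet-stable; the `seed` column is left `NA` until
#' [group_by_seed()] fills it.
#'
#' @param path Path to the table (TSV, or CSV by sniffing).
#' @return A `data.table` with columns `sirna_id`, `gene`, `guide_sequence`
#'   (RNA alphabet), `seed` (`NA`).
#' @details Guides must be 19-23 nt over A/C/G/U (or T). Characters outside
#'   that alphabet, out-of-range lengths, duplicate `sirna_id`s and empty
#'   gene symbols are hard errors.
#' @export
read_library <- function(path) {
  dt <- .read_delim(path)
  need <- c("sirna_id", "gene", "guide_sequence")
  miss <- setdiff(need, names(dt))
  if (length(miss)) {
    stop("library table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  guide <- chartr("T", "U", toupper(as.character(dt$guide_sequence)))
  bad <- grepl("[^ACGU]", guide)
  if (any(bad)) {
    stop("guide sequence with non-ACGU/T character in row ", which(bad)[1],
         " of ", path)
  }
  len <- nchar(guide)
  if (any(len < 19L | len > 23L)) {
    i <- which(len < 19L | len > 23L)[1]
    stop("guide length ", len[i], " outside [19, 23] in row ", i, " of ", path)
  }
  id <- as.character(dt$sirna_id)
  if (anyDuplicated(id)) {
    stop("duplicate sirna_id '", id[duplicated(id)][1], "' in ", path)
  }
  gene <- as.character(dt$gene)
  if (any(is.na(gene) | gene == "")) {
    stop("empty gene symbol in row ", which(is.na(gene) | gene == "")[1],
         " of ", path)
  }
  data.table(sirna_id = id, gene = gene, guide_sequence = guide,
             seed = NA_character_)
}

#' Read an expression table
#'
#' Required columns: `gene`, `fpkm`; optional `cell_line` and
#' `expected_count`. Negative FPKM is a hard error.
#'
#' @param path Path to the table.
#' @return A `data.table` with at least `gene` and `fpkm`.
#' @export
read_expression <- function(path) {
  dt <- .read_delim(path)
  miss <- setdiff(c("gene", "fpkm"), names(dt))
  if (length(miss)) {
    stop("expression table ", path, " is missing column(s): ",
         paste(miss, collapse = ", "))
  }
  dt[, fpkm := as.numeric(fpkm)]
  if (any(dt$fpkm < 0, na.rm = TRUE)) {
    stop("negative FPKM in row ", which(dt$fpkm < 0)[1], " of ", path)
  }
  dt[]
}

#' Read 3'-UTR sequences from FASTA
#'
#' The first whitespace-delimited token of each header is taken as the gene
#' symbol. Sequences are upper-cased DNA over A/C/G/T/N. When a gene appears
#' more than once the longest record is kept with a warning.
#'
#' @param path FASTA file.
#' @return Named character vector, gene symbol -> UTR sequence.
#' @export
read_fasta_utrs <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  genes <- vapply(strsplit(names(ss), "\\s+"), `[`, character(1), 1L)
  names(seqs) <- genes
  if (anyDuplicated(genes)) {
    warning("duplicate gene header(s) in ", path, "; keeping longest record")
    ord <- order(-nchar(seqs))
    seqs <- seqs[ord][!duplicated(genes[ord])]
  }
  seqs
}

#' Write named sequences to FASTA
#'
#' @param seqs Named character vector (name -> DNA sequence).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  ss <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

#' Write a result table
#'
#' Writes gene-level or dose-response results as TSV with a deterministic
#' column order (as given) and numeric columns at fixed precision, so the
#' same records always produce byte-identical files and the file re-reads to
#' an equal collection.
#'
#' @param records A data.frame of results.
#' @param path Output path.
#' @param digits Significant digits kept for numeric columns.
#' @return `path`, invisibly.
#' @export
write_results <- function(records, path, digits = 10L) {
  records <- as.data.table(records)
  out <- copy(records)
  for (col in names(out)) {
    if (is.double(out[[col]])) {
      set(out, j = col, value = sprintf(paste0("%.", digits, "g"), out[[col]]))
      set(out, j = col, value = sub("^NA$", "", out[[col]]))
    }
  }
  fwrite(out, path, sep = "\t", quote = FALSE, na = "")
  invisible(path)
}

#' Read a result table written by [write_results()]
#'
#' @param path Path to the TSV.
#' @return A `data.table`.
#' @export
read_results <- function(path) {
  .read_delim(path)
}

# sniff TSV vs CSV from the header line, then read with data.table
.read_delim <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  fread(path, sep = sep, header = TRUE, colClasses = NULL,
        data.table = TRUE, na.strings = c("NA", ""))
}

#' Parse well addresses
#'
#' Accepts "A01"-style letter-number addresses (one or two leading letters,
#' supporting 1536-well "AA"-"AF" rows) or "row:col" integer pairs.
#'
#' @param well Character vector of well addresses.
#' @return List with integer vectors `row` and `col`, 1-based.
#' @export
parse_well <- function(well) {
  well <- toupper(trimws(well))
  row <- integer(length(well))
  col <- integer(length(well))
  alpha <- grepl("^[A-Z]{1,2}[0-9]+$", well)
  pair <- grepl("^[0-9]+:[0-9]+$", well)
  bad <- !(alpha | pair)
  if (any(bad)) stop("unparseable well address '", well[bad][1], "'")
  if (any(alpha)) {
    letters_part <- sub("[0-9]+$", "", well[alpha])
    n1 <- nchar(letters_part) == 1L
    val <- ifelse(n1,
                  match(letters_part, LETTERS),
                  26L + (match(substr(letters_part, 1, 1), LETTERS) - 1L) * 26L +
                    match(substr(letters_part, 2, 2), LETTERS))
    row[alpha] <- as.integer(val)
    col[alpha] <- as.integer(sub("^[A-Z]+", "", well[alpha]))
  }
  if (any(pair)) {
    parts <- strsplit(well[pair], ":", fixed = TRUE)
    row[pair] <- as.integer(vapply(parts, `[`, character(1), 1L))
    col[pair] <- as.integer(vapply(parts, `[`, character(1), 2L))
  }
  if (any(row < 1L) || any(col < 1L)) stop("well addresses are 1-based")
  list(row = row, col = col)
}

#' Format (row, col) well coordinates as letter-number addresses
#'
#' @param row,col 1-based integer vectors.
#' @return Character vector like "A01"; rows beyond 26 use two letters.
#' @export
format_well <- function(row, col) {
  lab <- ifelse(row <= 26L, LETTERS[row],
                paste0(LETTERS[(row - 27L) %/% 26L + 1L],
                       LETTERS[(row - 27L) %% 26L + 1L]))
  paste0(lab, sprintf("%02d", col))
}
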