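#' Extract the seed sequence of a mature miRNA
#'
#' The seed is the 6-mer at positions 2-7 (1-based) of the mature
#' sequence; near-perfect Watson-Crick pairing of the seed with an mRNA
#' drives canonical targeting, so matures sharing a seed form a family.
#'
#' @param sequence character vector of RNA sequences (A/C/G/U), each of
#'   length at least 7 nt.
#' @return character vector of 6-mers.
#' @examples
#' extract_seed("UAGCACCAUCU")  # the miR-29 family seed, AGCACC
#' @export
extract_seed <- function(sequence) {
  sequence <- as.character(sequence)
  short <- nchar(sequence) < 7L
  if (any(short)) {
    stop("sequence(s) shorter than 7 nt: ",
         paste(utils::head(sequence[short], 5L), collapse = ", "))
  }
  substr(sequence, 2L, 7L)
}

#' Parse a miRBase-style mature-sequence FASTA file
#'
#' Reads mature miRNA sequences, derives the seed (positions 2-7) for
#' each, and parses the 3-letter species code from the name prefix.
#' DNA-alphabet files are tolerated: `T` is converted to `U` with a
#' warning.  Gzip-compressed input is accepted.
#'
#' @param path path to a FASTA file.  The first whitespace-delimited token
#'   of each header is taken as the mature name.
#' @return a `mature_set` data.frame with columns `id`, `species_code`,
#'   `sequence`, `seed` and a list-column `precursor_ids` (filled in by
#'   [parse_locus_gff3()] linkage at network-build time).
#' @seealso [parse_locus_gff3()], [write_mature_fasta()]
#' @export
parse_mature_fasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  seqs <- Biostrings::readBStringSet(path)
  if (length(seqs) == 0L) {
    warning("no FASTA records in ", path)
    return(mature_set(character(), character(), character()))
  }
  headers <- names(seqs)
  ids <- vapply(strsplit(trimws(headers), "\\s+"), `[`, character(1), 1L)
  bad <- is.na(ids) | !nzchar(ids)
  if (any(bad)) {
    stop("malformed FASTA header at record(s) ",
         paste(which(bad), collapse = ", "))
  }
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicated mature id(s): ", paste(dup, collapse = ", "))
  }
  sq <- toupper(as.character(seqs))
  if (any(grepl("T", sq, fixed = TRUE))) {
    warning("sequences contain 'T'; converted to 'U' (DNA-alphabet input): ",
            paste(utils::head(ids[grepl("T", sq, fixed = TRUE)], 5L),
                  collapse = ", "))
    sq <- gsub("T", "U", sq, fixed = TRUE)
  }
  badalpha <- grepl("[^ACGU]", sq)
  if (any(badalpha)) {
    stop("non-A/C/G/U characters in sequence(s): ",
         paste(ids[badalpha], collapse = ", "))
  }
  short <- nchar(sq) < 7L
  if (any(short)) {
    stop("sequence shorter than 7 nt for id(s): ",
         paste(ids[short], collapse = ", "))
  }
  species <- ifelse(grepl("^[A-Za-z]{3}-", ids),
                    tolower(substr(ids, 1L, 3L)), NA_character_)
  if (anyNA(species)) {
    warning("no 3-letter species prefix for id(s): ",
            paste(utils::head(ids[is.na(species)], 5L), collapse = ", "))
  }
  mature_set(ids, species, sq)
}

# internal constructor for the mature_set container
mature_set <- function(id, species_code, sequence,
                       precursor_ids = rep(list(character()), length(id))) {
  out <- data.frame(id = id, species_code = species_code,
                    sequence = sequence,
                    seed = if (length(id)) extract_seed(sequence) else character(),
                    stringsAsFactors = FALSE)
  out$precursor_ids <- precursor_ids
  class(out) <- c("mature_set", "data.frame")
  out
}

#' Write a mature set back to FASTA
#'
#' @param matures a `mature_set` from [parse_mature_fasta()].
#' @param path output path (`.gz` suffix compresses).
#' @return `path`, invisibly.
#' @export
write_mature_fasta <- function(matures, path) {
  x <- Biostrings::BStringSet(setNames(matures$sequence, matures$id))
  Biostrings::writeXStringSet(x, filepath = path,
                              compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Parse miRBase-style genome coordinates (GFF3)
#'
#' Expects the miRBase genome-coordinate dialect: feature type
#' `miRNA_primary_transcript` for precursor hairpins and `miRNA` for
#' mature products, linked by the `Derives_from` attribute.  GFF3
#' coordinates are 1-based inclusive at the file boundary and converted to
#' the package-internal 0-based half-open convention immediately after
#' parsing; all distance arithmetic uses the internal convention.
#'
#' @param path path to a GFF3 file (optionally gzipped).
#' @return a `locus_set` data.frame with columns `id`, `chrom`, `start`,
#'   `end` (0-based half-open), `strand` and list-column `mature_ids`
#'   (mature names whose `miRNA` features derive from the precursor).
#' @export
parse_locus_gff3 <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  if (length(gr) == 0L) {
    warning("no features in ", path)
    return(locus_set(character(), character(), integer(), integer(),
                     character()))
  }
  mc <- S4Vectors::mcols(gr)
  type <- as.character(mc$type)
  get_attr <- function(col) {
    if (!col %in% names(mc)) return(rep(NA_character_, length(gr)))
    v <- mc[[col]]
    if (methods::is(v, "List") || is.list(v)) {
      vapply(v, function(x) if (length(x)) as.character(x[[1L]]) else NA_character_,
             character(1))
    } else as.character(v)
  }
  ids <- get_attr("ID")
  nms <- get_attr("Name")
  der <- get_attr("Derives_from")
  lab <- ifelse(is.na(nms), ids, nms)

  is_pre <- type == "miRNA_primary_transcript"
  is_mat <- type == "miRNA"
  if (!any(is_pre)) stop("no miRNA_primary_transcript features in ", path)
  pre_id <- ifelse(is.na(ids[is_pre]), nms[is_pre], ids[is_pre])
  if (anyNA(pre_id)) stop("precursor feature without ID or Name attribute")
  if (anyDuplicated(pre_id)) {
    stop("duplicated precursor id(s): ",
         paste(unique(pre_id[duplicated(pre_id)]), collapse = ", "))
  }
  dangling <- is_mat & !(der %in% pre_id)
  if (any(dangling)) {
    stop("miRNA feature(s) with missing or dangling Derives_from: ",
         paste(lab[dangling], collapse = ", "))
  }
  s1 <- GenomicRanges::start(gr)[is_pre]
  e1 <- GenomicRanges::end(gr)[is_pre]
  if (any(s1 > e1)) stop("precursor with start > end")
  mature_by_pre <- split(lab[is_mat], factor(der[is_mat], levels = pre_id))
  locus_set(id = pre_id,
            chrom = as.character(GenomicRanges::seqnames(gr))[is_pre],
            start = s1 - 1L,             # to 0-based half-open
            end = e1,
            strand = as.character(GenomicRanges::strand(gr))[is_pre],
            mature_ids = unname(as.list(mature_by_pre)))
}

# internal constructor for the locus_set container
locus_set <- function(id, chrom, start, end, strand,
                      mature_ids = rep(list(character()), length(id))) {
  strand[!strand %in% c("+", "-")] <- NA_character_
  out <- data.frame(id = id, chrom = chrom,
                    start = as.integer(start), end = as.integer(end),
                    strand = strand, stringsAsFactors = FALSE)
  out$mature_ids <- mature_ids
  if (nrow(out) && any(out$end < out$start)) stop("locus with end < start")
  class(out) <- c("locus_set", "data.frame")
  out
}

#' Write a locus set back to GFF3
#'
#' Emits one `miRNA_primary_transcript` feature per precursor plus one
#' `miRNA` child feature per linked mature name (at the precursor's
#' coordinates; mature-level coordinates are not retained by the parser).
#' Internal 0-based half-open coordinates are converted back to GFF3
#' 1-based inclusive at this boundary.
#'
#' @param loci a `locus_set` from [parse_locus_gff3()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_locus_gff3 <- function(loci, path) {
  if (nrow(loci) == 0L) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  n_mat <- vapply(loci$mature_ids, length, integer(1))
  pre <- GenomicRanges::GRanges(
    seqnames = loci$chrom,
    ranges = IRanges::IRanges(start = loci$start + 1L, end = loci$end),
    strand = ifelse(is.na(loci$strand), "*", loci$strand))
  S4Vectors::mcols(pre)$type <- rep("miRNA_primary_transcript", nrow(loci))
  S4Vectors::mcols(pre)$ID <- loci$id
  S4Vectors::mcols(pre)$Name <- loci$id
  S4Vectors::mcols(pre)$Derives_from <- rep(NA_character_, nrow(loci))
  keep <- rep(seq_len(nrow(loci)), n_mat)
  mat <- pre[keep]
  S4Vectors::mcols(mat)$type <- rep("miRNA", length(mat))
  mat_names <- unlist(loci$mature_ids, use.names = FALSE)
  S4Vectors::mcols(mat)$ID <- paste0(mat_names, "_", seq_along(mat))
  S4Vectors::mcols(mat)$Name <- mat_names
  S4Vectors::mcols(mat)$Derives_from <- loci$id[keep]
  all <- c(pre, mat)
  rtracklayer::export(all, path, format = "gff3")
  invisible(path)
}

#' Parse a miRNA-to-target prediction table
#'
#' Accepts either a long two-column TSV (mature id, gene id; one pair per
#' row) or a wide two-column TSV whose second column holds a
#' comma-separated gene list.  The format is auto-detected from the cell
#' contents.  Target sets are deduplicated; ids with empty target sets
#' are retained and flagged.
#'
#' @param path path to the table (optionally gzipped); a header row is
#'   required.
#' @param source_label free-text provenance label stored on the result.
#' @return a `target_table`: list with elements `source_label` and
#'   `targets` (named list mapping mature id to a character vector of
#'   gene ids), with attribute `empty_ids`.
#' @export
parse_target_table <- function(path, source_label = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          colClasses = "character", check.names = FALSE,
                          quote = "", comment.char = "")
  if (ncol(df) != 2L) {
    stop("unknown target-table format (expected 2 tab-separated columns, ",
         "got ", ncol(df), ") at line 1 of ", path)
  }
  id <- trimws(df[[1L]])
  val <- trimws(df[[2L]])
  wide <- any(grepl(",", val, fixed = TRUE))
  if (wide) {
    genes <- lapply(strsplit(val, ","), function(g) {
      g <- trimws(g)
      unique(g[nzchar(g)])
    })
    if (anyDuplicated(id)) {
      # same id on several wide rows: union
      genes <- lapply(split(genes, id), function(x) unique(unlist(x)))
      targets <- genes[unique(id)]
    } else {
      targets <- setNames(genes, id)
    }
  } else {
    keep <- nzchar(id)
    targets <- lapply(split(val[keep], id[keep]),
                      function(g) unique(g[nzchar(g)]))
    targets <- targets[unique(id[keep])]
  }
  empty <- names(targets)[vapply(targets, length, integer(1)) == 0L]
  if (length(empty)) {
    message(length(empty), " miRNA(s) with empty target sets retained: ",
            paste(utils::head(empty, 5L), collapse = ", "))
  }
  message("parsed ", length(targets), " target set(s); ",
          sum(vapply(targets, length, integer(1))), " target assignments")
  structure(list(source_label = source_label, targets = targets),
            empty_ids = empty, class = "target_table")
}

#' Parse a per-miRNA numeric score table
#'
#' Reads a delimited text table (TSV, CSV or semicolon-separated;
#' auto-detected from the header line unless `config$sep` is given) with
#' one row per mature miRNA.  All non-id columns are coerced to numeric;
#' non-numeric cells become missing values (never silently zero).  Ids
#' are kept verbatim and additionally stored as a normalized lookup key
#' (see [normalize_mirna_id()]).  If `annotation` is supplied, the match
#' report `rows_in = rows_matched + rows_unmatched` is attached and an
#' error with a species-mismatch hint is raised when nothing matches.
#'
#' @param path path to the table (optionally gzipped).
#' @param id_column name of the column holding mature miRNA ids.
#' @param config list of options: `sep` (NULL = auto), `dec` (decimal
#'   mark, default `"."`), `na_strings`.
#' @param annotation optional `mature_set` to match ids against.
#' @return a `score_table` data.frame: columns `id`, `id_norm`, then one
#'   numeric column per measurement; attribute `match_report` when
#'   `annotation` is given.
#' @export
parse_score_table <- function(path, id_column, config = list(),
                              annotation = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- config$sep
  dec <- config$dec %||% "."
  na_strings <- config$na_strings %||% c("NA", "NaN", "na", "")
  if (is.null(sep)) {
    con <- open_text(path)
    first <- readLines(con, n = 1L)
    close(con)
    sep <- if (grepl("\t", first)) "\t"
           else if (grepl(";", first, fixed = TRUE)) ";"
           else ","
  }
  df <- utils::read.delim(path, header = TRUE, sep = sep,
                          colClasses = "character", check.names = FALSE,
                          na.strings = na_strings, quote = "\"",
                          comment.char = "")
  if (!id_column %in% names(df)) {
    stop("id column '", id_column, "' not found; available columns: ",
         paste(names(df), collapse = ", "))
  }
  ids <- trimws(df[[id_column]])
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stop("duplicated miRNA id row(s): ", paste(dup, collapse = ", "))
  }
  value_cols <- setdiff(names(df), id_column)
  out <- data.frame(id = ids, id_norm = normalize_mirna_id(ids),
                    stringsAsFactors = FALSE)
  for (col in value_cols) {
    v <- df[[col]]
    if (dec != ".") v <- gsub(dec, ".", v, fixed = TRUE)
    num <- suppressWarnings(as.numeric(v))
    n_coerced <- sum(is.na(num) & !is.na(v))
    if (n_coerced > 0L) {
      message("column '", col, "': ", n_coerced,
              " non-numeric cell(s) set to missing")
    }
    out[[col]] <- num
  }
  class(out) <- c("score_table", "data.frame")
  if (!is.null(annotation)) {
    ann_norm <- normalize_mirna_id(annotation$id)
    matched <- out$id_norm %in% ann_norm
    report <- list(rows_in = nrow(out),
                   rows_matched = sum(matched),
                   rows_unmatched = sum(!matched),
                   unmatched_ids = out$id[!matched])
    if (report$rows_matched == 0L) {
      stop("none of ", nrow(out), " score-table ids match the annotation; ",
           "check that the species (id prefix) is correct")
    }
    message(report$rows_matched, "/", report$rows_in,
            " score rows matched the annotation (",
            report$rows_unmatched, " unmatched)")
    attr(out, "match_report") <- report
  }
  out
}

#' Build a score table from an in-memory data.frame
#'
#' @param df data.frame with an id column and numeric measurement columns.
#' @param id_column name of the id column.
#' @return a `score_table`.
#' @export
as_score_table <- function(df, id_column = "id") {
  stopifnot(id_column %in% names(df))
  ids <- as.character(df[[id_column]])
  if (anyDuplicated(ids)) {
    stop("duplicated miRNA id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }
  out <- data.frame(id = ids, id_norm = normalize_mirna_id(ids),
                    stringsAsFactors = FALSE)
  for (col in setdiff(names(df), c(id_column, "id_norm"))) {
    out[[col]] <- as.numeric(df[[col]])
  }
  class(out) <- c("score_table", "data.frame")
  out
}

#' Collapse replicate columns to per-condition log2 means
#'
#' Raw (non-negative) measurements are log2-transformed with a
#' pseudo-count and averaged across replicate columns of the same
#' condition, producing one output column per condition — the collapse
#' used for expression compendia shown on a 0-20 log2 scale.
#'
#' @param raw a `score_table` of non-negative raw values.
#' @param groups named character vector mapping replicate column name to
#'   condition label.
#' @param pseudo_count added before log2 (default 1) so zero counts map
#'   to 0.
#' @return a `score_table` with columns `id`, `id_norm` and one column
#'   per condition.
#' @export
collapse_log2_mean <- function(raw, groups, pseudo_count = 1) {
  stopifnot(inherits(raw, "score_table"))
  missing_cols <- setdiff(names(groups), names(raw))
  if (length(missing_cols)) {
    stop("replicate column(s) not in table: ",
         paste(missing_cols, collapse = ", "))
  }
  vals <- as.matrix(raw[, names(groups), drop = FALSE])
  if (any(vals < 0, na.rm = TRUE)) stop("negative raw value(s); raw scores must be >= 0")
  lv <- log2(vals + pseudo_count)
  out <- raw[, c("id", "id_norm")]
  for (cond in unique(groups)) {
    cols <- names(groups)[groups == cond]
    out[[cond]] <- rowMeans(lv[, cols, drop = FALSE], na.rm = TRUE)
    out[[cond]][is.nan(out[[cond]])] <- NA_real_
  }
  class(out) <- c("score_table", "data.frame")
  out
}
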