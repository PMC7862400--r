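## Readers and writers for every external format the pipeline touches.
## All external formats use 1-based inclusive coordinates (HMMER / Swiss-Prot /
## BLAST convention); interval arithmetic elsewhere in the package receives
## these coordinates unchanged and IRanges handles them as closed intervals.

.AA_ALPHABET <- c(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]], "X", "B", "Z", "U")

.fmt_error <- function(path, line, what) {
  stop(sprintf("format error in '%s' at line %d: %s", path, line, what),
       call. = FALSE)
}

#' Read protein sequences from a FASTA file
#'
#' The token before the first whitespace in each header is the protein
#' identifier. Residues are restricted to the 20 standard amino acids plus
#' X, B, Z and U; anything else is a format error that names the offending
#' line.
#'
#' @param path path to a FASTA file.
#' @return A \link[Biostrings]{AAStringSet} named by protein identifier
#'   (empty for an empty file).
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^\\s*$", lines)
  ids <- character(0); seqs <- character(0)
  cur_id <- NULL; cur_seq <- character(0)
  flush <- function() {
    if (!is.null(cur_id)) { ids <<- c(ids, cur_id); seqs <<- c(seqs, paste(cur_seq, collapse = "")) }
  }
  for (i in seq_along(lines)) {
    if (!keep[i]) next
    ln <- lines[i]
    if (startsWith(ln, ">")) {
      flush()
      hdr <- sub("^>\\s*", "", ln)
      cur_id <- strsplit(hdr, "\\s+")[[1]][1]
      if (is.na(cur_id) || !nzchar(cur_id))
        .fmt_error(path, i, "malformed FASTA header (empty identifier)")
      cur_seq <- character(0)
    } else {
      if (is.null(cur_id))
        .fmt_error(path, i, "sequence data before any header")
      res <- toupper(gsub("\\s", "", ln))
      bad <- setdiff(strsplit(res, "")[[1]], .AA_ALPHABET)
      if (length(bad))
        .fmt_error(path, i, paste0("illegal residue(s): ",
                                   paste(unique(bad), collapse = ", ")))
      cur_seq <- c(cur_seq, res)
    }
  }
  flush()
  if (!length(ids)) return(Biostrings::AAStringSet())
  if (anyDuplicated(ids))
    stop("duplicate protein identifiers in ", path, call. = FALSE)
  out <- Biostrings::AAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write an AAStringSet (or named character vector) as FASTA
#' @param x sequences, named by protein identifier.
#' @param path output path.
#' @export
writeFasta <- function(x, path) {
  nm <- names(x)
  x <- as.character(x)
  if (is.null(nm)) nm <- names(x)
  if (is.null(nm)) stop("sequences must be named by protein identifier",
                        call. = FALSE)
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_along(x))
    writeLines(c(paste0(">", nm[i]), x[[i]]), con)
  invisible(path)
}

#' Read per-residue disorder score tables
#'
#' Accepts the IUPred-style layout: a comment line \code{# <protein_id>}
#' opening each protein followed by whitespace-separated rows
#' \code{position residue score}, positions contiguous from 1; or a
#' two-column dialect with one row per protein,
#' \code{protein_id<TAB>comma-separated scores}. A residue is called
#' disordered iff its score strictly exceeds \code{threshold}.
#'
#' @param path path to the score table.
#' @param threshold call threshold in (0, 1); default 0.5.
#' @return A named list of \linkS4class{DisorderProfile} objects.
#' @export
readDisorderScores <- function(path, threshold = 0.5) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (threshold <= 0 || threshold >= 1)
    stop("'threshold' must be in (0, 1)", call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  nonblank <- which(!grepl("^\\s*$", lines))
  if (!length(nonblank)) return(list())
  has_comment <- any(startsWith(lines[nonblank], "#"))
  profiles <- list()
  if (!has_comment &&
      all(lengths(strsplit(trimws(lines[nonblank]), "\\s+")) == 2L)) {
    ## two-column dialect: protein_id <ws> s1,s2,...
    for (i in nonblank) {
      f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
      sc <- suppressWarnings(as.numeric(strsplit(f[2], ",")[[1]]))
      if (anyNA(sc)) .fmt_error(path, i, "non-numeric score")
      if (any(sc < 0 | sc > 1)) .fmt_error(path, i, "score outside [0, 1]")
      profiles[[f[1]]] <- DisorderProfile(f[1], scores = sc,
                                          threshold = threshold)
    }
    return(profiles)
  }
  cur_id <- NULL; cur_scores <- numeric(0)
  flush <- function(line) {
    if (is.null(cur_id)) return()
    if (!length(cur_scores))
      .fmt_error(path, line, paste0("no score rows for protein ", cur_id))
    profiles[[cur_id]] <<- DisorderProfile(cur_id, scores = cur_scores,
                                           threshold = threshold)
  }
  for (i in seq_along(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln)) next
    if (startsWith(ln, "#")) {
      flush(i)
      cur_id <- strsplit(sub("^#\\s*", "", ln), "\\s+")[[1]][1]
      if (is.na(cur_id) || !nzchar(cur_id))
        .fmt_error(path, i, "comment separator without protein identifier")
      cur_scores <- numeric(0)
    } else {
      if (is.null(cur_id))
        .fmt_error(path, i, "score row before any '# protein' separator")
      f <- strsplit(ln, "\\s+")[[1]]
      if (length(f) < 3L) .fmt_error(path, i, "expected: position residue score")
      pos <- suppressWarnings(as.integer(f[1]))
      sc <- suppressWarnings(as.numeric(f[3]))
      if (is.na(pos) || pos != length(cur_scores) + 1L)
        .fmt_error(path, i, "non-contiguous residue positions")
      if (is.na(sc)) .fmt_error(path, i, "non-numeric score")
      if (sc < 0 || sc > 1) .fmt_error(path, i, "score outside [0, 1]")
      cur_scores <- c(cur_scores, sc)
    }
  }
  flush(length(lines))
  profiles
}

#' Write disorder profiles in the IUPred-style layout
#' @param profiles named list of \linkS4class{DisorderProfile}.
#' @param path output path.
#' @param sequences optional named character vector of sequences used to fill
#'   the residue column; '*' is written when absent.
#' @export
writeDisorderScores <- function(profiles, path, sequences = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  for (p in profiles) {
    sc <- disorderScores(p)
    if (is.null(sc)) sc <- ifelse(disorderCalls(p), 0.75, 0.25)
    res <- if (!is.null(sequences) && proteinId(p) %in% names(sequences))
      strsplit(as.character(sequences[[proteinId(p)]]), "")[[1]]
    else rep("*", length(p))
    writeLines(paste0("# ", proteinId(p)), con)
    writeLines(sprintf("%d\t%s\t%.6f", seq_along(sc), res, sc), con)
  }
  invisible(path)
}

#' Read HMMER3 per-domain output (domtblout)
#'
#' Parses the 23-column \code{--domtblout} layout written by
#' \code{hmmscan} (target = Pfam model, query = protein). Envelope
#' coordinates (columns 20-21) define the domain boundaries. Rows failing
#' either E-value filter are dropped; the filters are strict
#' (values must be below the cutoffs).
#'
#' @param path path to a domtblout file.
#' @param maxFullEvalue full-sequence E-value cutoff (default 0.01).
#' @param maxCEvalue conditional E-value cutoff (default 0.01).
#' @return data.frame with columns protein_id, family_id, family_name,
#'   start, end, full_evalue, c_evalue.
#' @export
readDomtblout <- function(path, maxFullEvalue = 0.01, maxCEvalue = 0.01) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  rows <- which(!startsWith(lines, "#") & !grepl("^\\s*$", lines))
  out <- vector("list", length(rows))
  for (j in seq_along(rows)) {
    i <- rows[j]
    f <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    if (length(f) < 22L)
      .fmt_error(path, i, sprintf(
        "expected >= 22 whitespace-delimited columns (domtblout), found %d",
        length(f)))
    out[[j]] <- data.frame(
      protein_id  = f[4],
      family_id   = sub("\\.\\d+$", "", f[2]),
      family_name = f[1],
      start       = as.integer(f[20]),
      end         = as.integer(f[21]),
      full_evalue = as.numeric(f[7]),
      c_evalue    = as.numeric(f[12]),
      stringsAsFactors = FALSE)
  }
  dom <- if (length(out)) do.call(rbind, out) else
    data.frame(protein_id = character(0), family_id = character(0),
               family_name = character(0), start = integer(0),
               end = integer(0), full_evalue = numeric(0),
               c_evalue = numeric(0))
  if (anyNA(dom$start) || anyNA(dom$end) || anyNA(dom$full_evalue) ||
      anyNA(dom$c_evalue))
    stop("format error in '", path, "': non-numeric coordinate or E-value",
         call. = FALSE)
  filterDomains(dom, maxFullEvalue, maxCEvalue)
}

#' Apply the domain E-value filter
#'
#' Retains instances with full-sequence E value and conditional E value
#' both strictly below the cutoffs.
#' @param domains domain-instance data.frame (see \code{\link{readDomtblout}}).
#' @param maxFullEvalue,maxCEvalue strict upper cutoffs (default 0.01).
#' @export
filterDomains <- function(domains, maxFullEvalue = 0.01, maxCEvalue = 0.01) {
  keep <- domains$full_evalue < maxFullEvalue & domains$c_evalue < maxCEvalue
  out <- domains[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a domain table in HMMER3 domtblout layout
#' @param domains domain-instance data.frame.
#' @param path output path.
#' @param proteinLengths optional named integer vector (qlen column).
#' @export
writeDomtblout <- function(domains, path, proteinLengths = NULL) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines("# target name, accession, tlen, query name, accession, qlen, full E-value, score, bias, #, of, c-Evalue, i-Evalue, score, bias, hmm from, hmm to, ali from, ali to, env from, env to, acc, description",
             con)
  n <- nrow(domains)
  if (n) {
    qlen <- if (is.null(proteinLengths)) rep(0L, n) else
      as.integer(proteinLengths[domains$protein_id])
    tlen <- domains$end - domains$start + 1L
    writeLines(sprintf(
      "%s %s %d %s - %d %.3g %.1f %.1f %d %d %.3g %.3g %.1f %.1f %d %d %d %d %d %d %.2f -",
      domains$family_name, domains$family_id, tlen, domains$protein_id, qlen,
      domains$full_evalue, 50, 0.1, 1L, 1L, domains$c_evalue,
      domains$c_evalue, 50, 0.1, 1L, tlen,
      domains$start, domains$end, domains$start, domains$end, 0.9), con)
  }
  invisible(path)
}

#' Read BLAST tabular alignments
#'
#' Expects \code{-outfmt "6 qseqid sseqid pident length qlen slen qstart
#' qend sstart send evalue"} (11 columns). \code{qlen}/\code{slen} are
#' required because the repeat-similarity score needs the full query and
#' subject lengths.
#'
#' @param path path to the tabular file.
#' @return data.frame with one row per HSP.
#' @export
readBlastTabular <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  rows <- which(!startsWith(lines, "#") & !grepl("^\\s*$", lines))
  if (!length(rows))
    return(data.frame(query_id = character(0), subject_id = character(0),
                      identity_pct = numeric(0), align_len = integer(0),
                      query_len = integer(0), subject_len = integer(0),
                      q_start = integer(0), q_end = integer(0),
                      s_start = integer(0), s_end = integer(0),
                      evalue = numeric(0)))
  fields <- strsplit(trimws(lines[rows]), "\\s+")
  nf <- lengths(fields)
  if (any(nf != 11L))
    .fmt_error(path, rows[which(nf != 11L)[1]],
               paste0("expected 11 columns; rerun blastp with -outfmt ",
                      "\"6 qseqid sseqid pident length qlen slen qstart ",
                      "qend sstart send evalue\""))
  m <- do.call(rbind, fields)
  out <- data.frame(
    query_id = m[, 1], subject_id = m[, 2],
    identity_pct = as.numeric(m[, 3]), align_len = as.integer(m[, 4]),
    query_len = as.integer(m[, 5]), subject_len = as.integer(m[, 6]),
    q_start = as.integer(m[, 7]), q_end = as.integer(m[, 8]),
    s_start = as.integer(m[, 9]), s_end = as.integer(m[, 10]),
    evalue = as.numeric(m[, 11]), stringsAsFactors = FALSE)
  if (any(out$identity_pct < 0 | out$identity_pct > 100, na.rm = TRUE))
    stop("format error in '", path, "': identity outside [0, 100]",
         call. = FALSE)
  if (any(out$q_start > out$q_end, na.rm = TRUE))
    stop("format error in '", path, "': q_start > q_end", call. = FALSE)
  out
}

#' Read a ranked species-lineage table
#'
#' TSV with a header; first column \code{species_id}, remaining columns
#' ordered taxonomic ranks from root-most (e.g. superkingdom) to the
#' species itself. All species referenced by downstream analyses must
#' appear here.
#'
#' @param path path to the TSV.
#' @return data.frame (class \code{lineage_table}) whose rank columns are
#'   everything after \code{species_id}.
#' @export
readLineageTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE,
                           check.names = FALSE)
  if (ncol(tab) < 2L || names(tab)[1] != "species_id")
    stop("lineage table needs a 'species_id' column followed by ranked ",
         "taxon columns", call. = FALSE)
  if (anyDuplicated(tab$species_id))
    stop("duplicate species_id in lineage table", call. = FALSE)
  class(tab) <- c("lineage_table", "data.frame")
  tab
}

#' Read the cell-type-number table (organism complexity)
#' @param path TSV with columns species_id, cell_types.
#' @export
readCellTypeTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("species_id", "cell_types") %in% names(tab)))
    stop("cell-type table needs columns species_id, cell_types",
         call. = FALSE)
  tab$cell_types <- as.numeric(tab$cell_types)
  tab
}

#' Read a domain-family annotation table
#' @param path TSV with columns family_id, term.
#' @export
readAnnotationTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!all(c("family_id", "term") %in% names(tab)))
    stop("annotation table needs columns family_id, term", call. = FALSE)
  tab
}

#' Read a PTM site table
#' @param path TSV with columns protein_id, position, residue, mod_type.
#' @export
readPTMTable <- function(path) {
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "position", "residue", "mod_type")
  if (!all(need %in% names(tab)))
    stop("PTM table needs columns ", paste(need, collapse = ", "),
         call. = FALSE)
  tab$position <- as.integer(tab$position)
  tab
}

#' Extract MOD_RES sites and sequences from Swiss-Prot flat text
#'
#' Minimal parser handling only ID, AC, SQ and FT MOD_RES lines; every
#' other line type is ignored. The first accession on the first AC line is
#' the protein identifier.
#'
#' @param path Swiss-Prot text file (possibly many entries, '//'-separated).
#' @return list with \code{proteins} (data.frame protein_id, sequence) and
#'   \code{sites} (data.frame protein_id, position, residue, mod_type).
#'   The residue column is filled from the parsed sequence; a described
#'   modification residue that disagrees with the sequence triggers a
#'   warning, not an error.
#' @export
readSwissProtPTM <- function(path) {
  lines <- readLines(path, warn = FALSE)
  prot <- list(); sites <- list()
  acc <- NULL; in_seq <- FALSE; seq_chunks <- character(0)
  pend_pos <- NULL
  finish_entry <- function() {
    if (!is.null(acc))
      prot[[length(prot) + 1L]] <<- data.frame(
        protein_id = acc,
        sequence = gsub("\\s", "", paste(seq_chunks, collapse = "")),
        stringsAsFactors = FALSE)
    acc <<- NULL; in_seq <<- FALSE; seq_chunks <<- character(0)
    pend_pos <<- NULL
  }
  for (ln in lines) {
    tag <- substr(ln, 1, 2)
    if (tag == "//") { finish_entry(); next }
    if (tag == "AC" && is.null(acc)) {
      acc <- sub(";.*$", "", trimws(substr(ln, 6, nchar(ln))))
    } else if (tag == "SQ") {
      in_seq <- TRUE
    } else if (tag == "  " && in_seq) {
      seq_chunks <- c(seq_chunks, trimws(ln))
    } else if (tag == "FT") {
      body <- substr(ln, 6, nchar(ln))
      if (grepl("^MOD_RES", body)) {
        pend_pos <- suppressWarnings(
          as.integer(sub("^MOD_RES\\s+(\\d+).*$", "\\1", body)))
      } else if (!is.null(pend_pos) && grepl("/note=", body)) {
        mod <- trimws(sub('^.*?/note="([^";.]+).*$', "\\1", body))
        sites[[length(sites) + 1L]] <- data.frame(
          protein_id = acc, position = pend_pos, mod_type = mod,
          stringsAsFactors = FALSE)
        pend_pos <- NULL
      }
    }
  }
  finish_entry()
  proteins <- if (length(prot)) do.call(rbind, prot) else
    data.frame(protein_id = character(0), sequence = character(0))
  st <- if (length(sites)) do.call(rbind, sites) else
    data.frame(protein_id = character(0), position = integer(0),
               mod_type = character(0))
  ## fill residue column from the sequence; warn on disagreement with the
  ## residue implied by the modification description (e.g. Phosphoserine ~ S)
  st$residue <- NA_character_
  if (nrow(st)) {
    seqs <- stats::setNames(proteins$sequence, proteins$protein_id)
    st$residue <- substr(seqs[st$protein_id], st$position, st$position)
    if (any(!nzchar(st$residue) | is.na(st$residue)))
      warning("MOD_RES position outside sequence for ",
              sum(!nzchar(st$residue) | is.na(st$residue)), " site(s)")
    implied <- c(Phosphoserine = "S", Phosphothreonine = "T",
                 Phosphotyrosine = "Y")
    key <- intersect(st$mod_type, names(implied))
    bad <- st$mod_type %in% key & st$residue != implied[st$mod_type]
    bad[is.na(bad)] <- FALSE
    if (any(bad))
      warning(sum(bad), " MOD_RES site(s) disagree with the sequence residue")
  }
  list(proteins = proteins,
       sites = st[, c("protein_id", "position", "residue", "mod_type")])
}

#' Write a data.frame as a headered TSV
#' @param x data.frame.
#' @param path output path.
#' @export
writeTSV <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a lineage table
#' @param lineages a \code{lineage_table} data.frame.
#' @param path output path.
#' @export
writeLineageTable <- function(lineages, path) writeTSV(lineages, path)
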