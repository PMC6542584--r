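# IO for the external representations the pipeline touches:
# peptide tables (TSV), reference proteins (FASTA), spectra (MGF),
# labelled square matrices (TSV).

#' Validate a peptide table
#'
#' Checks the invariants of the de novo peptide table representation:
#' standard-alphabet sequences, ALC within \[0, 100\], modification positions
#' inside the peptide and on chemically plausible residues.
#'
#' @param t a `peptide_table` data.frame.
#' @return `t`, invisibly, if valid; otherwise an error naming the first
#'   offending row.
#' @export
validate_peptide_table <- function(t) {
  required <- c("sample_id", "peptide", "alc", "mods", "charge", "enzyme")
  missing <- setdiff(required, names(t))
  if (length(missing) > 0) {
    stop2("peptide table lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (nrow(t) == 0) return(invisible(t))
  ok <- is_standard_seq(t$peptide)
  if (!all(ok)) {
    i <- which(!ok)[1]
    bad <- gsub(paste0("[", paste(AA_ALPHABET, collapse = ""), "]"), "",
                t$peptide[i])
    stop2("row ", i, ": peptide '", t$peptide[i],
          "' contains non-standard residue(s) '", bad, "'")
  }
  if (any(is.na(t$alc)) || any(t$alc < 0 | t$alc > 100)) {
    stop2("row ", which(is.na(t$alc) | t$alc < 0 | t$alc > 100)[1],
          ": alc outside [0, 100]")
  }
  if (!all(t$enzyme %in% c("trypsin", "elastase", "unknown"))) {
    stop2("row ", which(!t$enzyme %in% c("trypsin", "elastase", "unknown"))[1],
          ": unknown enzyme")
  }
  for (i in seq_len(nrow(t))) {
    m <- parse_mods(t$mods[i])
    if (nrow(m) == 0) next
    if (!all(m$kind %in% MOD_KINDS)) {
      stop2("row ", i, ": unknown modification kind '",
            setdiff(m$kind, MOD_KINDS)[1], "'")
    }
    if (any(m$pos < 1 | m$pos > nchar(t$peptide[i]))) {
      stop2("row ", i, ": mod position outside peptide")
    }
    res <- substring(t$peptide[i], m$pos, m$pos)
    for (j in seq_along(res)) {
      if (!res[j] %in% MOD_TARGETS[[m$kind[j]]]) {
        stop2("row ", i, ": ", m$kind[j], " annotated on residue ", res[j],
              " at position ", m$pos[j])
      }
    }
  }
  invisible(t)
}

new_peptide_table <- function(sample_id = character(), peptide = character(),
                              alc = numeric(), mods = character(),
                              charge = integer(), enzyme = character()) {
  t <- data.frame(sample_id = as.character(sample_id),
                  peptide = as.character(peptide),
                  alc = as.numeric(alc),
                  mods = as.character(mods),
                  charge = as.integer(charge),
                  enzyme = as.character(enzyme),
                  stringsAsFactors = FALSE)
  class(t) <- c("peptide_table", "data.frame")
  t
}

#' Read a de novo peptide table
#'
#' Reads the package's TSV dialect: a header row with at least the columns
#' `sample_id`, `peptide`, `alc`, `mods`, `charge`, `enzyme`; unknown columns
#' are ignored and row order is preserved. Modifications are encoded
#' `"pos:kind;pos:kind"` with 1-based positions into the peptide.
#'
#' @param path path to a TSV file.
#' @return a `peptide_table` data.frame.
#' @export
read_peptide_table <- function(path) {
  if (!file.exists(path)) stop2("no such file: ", path)
  raw <- utils::read.delim(path, stringsAsFactors = FALSE,
                           colClasses = "character", check.names = FALSE)
  required <- c("sample_id", "peptide", "alc", "mods", "charge", "enzyme")
  missing <- setdiff(required, names(raw))
  if (length(missing) > 0) {
    stop2("peptide table ", path, " lacks column(s): ",
          paste(missing, collapse = ", "))
  }
  t <- new_peptide_table(
    sample_id = raw$sample_id,
    peptide = toupper(trimws(raw$peptide)),
    alc = as.numeric(raw$alc),
    mods = ifelse(is.na(raw$mods), "", trimws(raw$mods)),
    charge = suppressWarnings(as.integer(raw$charge)),
    enzyme = ifelse(!nzchar(trimws(raw$enzyme)), "unknown",
                    tolower(trimws(raw$enzyme)))
  )
  validate_peptide_table(t)
  t
}

#' Write a peptide table
#'
#' @param t a `peptide_table`.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
write_peptide_table <- function(t, path) {
  validate_peptide_table(t)
  utils::write.table(t, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

new_reference_set <- function(entry_id, description, taxon, clade, is_marker,
                              sequence) {
  r <- data.frame(entry_id = as.character(entry_id),
                  description = as.character(description),
                  taxon = as.character(taxon),
                  clade = as.character(clade),
                  is_marker = as.logical(is_marker),
                  sequence = as.character(sequence),
                  stringsAsFactors = FALSE)
  class(r) <- c("reference_set", "data.frame")
  r
}

#' Validate a reference set
#' @param r a `reference_set` data.frame.
#' @return `r`, invisibly.
#' @export
validate_reference_set <- function(r) {
  required <- c("entry_id", "description", "taxon", "clade", "is_marker",
                "sequence")
  missing <- setdiff(required, names(r))
  if (length(missing) > 0) {
    stop2("reference set lacks column(s): ", paste(missing, collapse = ", "))
  }
  if (anyDuplicated(r$entry_id)) {
    stop2("duplicate entry_id: ", r$entry_id[duplicated(r$entry_id)][1])
  }
  if (nrow(r) > 0) {
    if (any(!nzchar(r$sequence))) {
      stop2("empty sequence for entry ", r$entry_id[!nzchar(r$sequence)][1])
    }
    ok <- is_standard_seq(r$sequence)
    if (!all(ok)) {
      stop2("entry ", r$entry_id[!ok][1],
            ": sequence contains non-standard residues")
    }
  }
  invisible(r)
}

#' Read labelled reference proteins from FASTA
#'
#' Header convention: `>entry_id|taxon|clade[|marker]`. Missing fields default
#' to taxon `"unknown"`, clade `"unknown"` and a non-marker entry. Lowercase
#' residues are uppercased and `'*'` terminators stripped.
#'
#' @param path FASTA file path.
#' @return a `reference_set` data.frame.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop2("no such file: ", path)
  ss <- Biostrings::readBStringSet(path)
  headers <- names(ss)
  seqs <- toupper(gsub("\\*", "", as.character(ss)))
  if (any(!nzchar(seqs))) {
    stop2("empty sequence in FASTA record '",
          headers[!nzchar(seqs)][1], "'")
  }
  fields <- strsplit(headers, "|", fixed = TRUE)
  get_field <- function(f, i, default) {
    v <- if (length(f) >= i) trimws(f[i]) else ""
    if (nzchar(v)) v else default
  }
  r <- new_reference_set(
    entry_id = vapply(fields, get_field, "", i = 1L, default = ""),
    description = headers,
    taxon = vapply(fields, get_field, "", i = 2L, default = "unknown"),
    clade = vapply(fields, get_field, "", i = 3L, default = "unknown"),
    is_marker = vapply(fields, function(f)
      length(f) >= 4 && tolower(trimws(f[4])) == "marker", logical(1)),
    sequence = unname(seqs)
  )
  validate_reference_set(r)
  r
}

#' Write a reference set to FASTA
#'
#' @param r a `reference_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(r, path) {
  validate_reference_set(r)
  ss <- Biostrings::BStringSet(r$sequence)
  names(ss) <- paste(r$entry_id, r$taxon, r$clade,
                     ifelse(r$is_marker, "marker", "-"), sep = "|")
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

new_spectrum <- function(spectrum_id, precursor_mz, charge, mz, intensity) {
  if (length(mz) == 0) stop2("spectrum ", spectrum_id, " has no peaks")
  if (any(intensity < 0)) stop2("negative intensity in ", spectrum_id)
  o <- order(mz)
  structure(list(spectrum_id = spectrum_id,
                 precursor_mz = precursor_mz,
                 charge = as.integer(charge),
                 mz = mz[o], intensity = intensity[o]),
            class = "spectrum_record")
}

#' Read spectra from an MGF file
#'
#' Parses standard `BEGIN IONS`/`END IONS` blocks with `PEPMASS`, optional
#' `CHARGE` and `TITLE`, and `m/z intensity` peak lines. Peaks are returned
#' sorted ascending by m/z.
#'
#' @param path MGF file path.
#' @return a list of `spectrum_record` objects.
#' @export
read_mgf <- function(path) {
  if (!file.exists(path)) stop2("no such file: ", path)
  lines <- readLines(path)
  spectra <- list()
  i <- 1L
  n_seq <- 0L
  while (i <= length(lines)) {
    line <- trimws(lines[i])
    if (line == "BEGIN IONS") {
      title <- NA_character_
      pepmass <- NA_real_
      charge <- 1L
      mz <- numeric()
      inten <- numeric()
      i <- i + 1L
      closed <- FALSE
      while (i <= length(lines)) {
        l <- trimws(lines[i])
        if (l == "END IONS") {
          closed <- TRUE
          break
        } else if (startsWith(l, "TITLE=")) {
          title <- sub("^TITLE=", "", l)
        } else if (startsWith(l, "PEPMASS=")) {
          pepmass <- as.numeric(strsplit(sub("^PEPMASS=", "", l), "\\s+")[[1]][1])
        } else if (startsWith(l, "CHARGE=")) {
          charge <- as.integer(gsub("[^0-9]", "", l))
        } else if (grepl("^[0-9]", l)) {
          vals <- as.numeric(strsplit(l, "\\s+")[[1]])
          mz <- c(mz, vals[1])
          inten <- c(inten, if (length(vals) > 1) vals[2] else 1)
        }
        i <- i + 1L
      }
      if (!closed) stop2("unterminated BEGIN IONS block in ", path)
      if (is.na(pepmass)) stop2("spectrum block without PEPMASS in ", path)
      n_seq <- n_seq + 1L
      id <- if (!is.na(title)) title else sprintf("spectrum_%05d", n_seq)
      spectra[[length(spectra) + 1L]] <-
        new_spectrum(id, pepmass, charge, mz, inten)
    }
    i <- i + 1L
  }
  spectra
}

#' Write spectra to an MGF file
#'
#' @param spectra list of `spectrum_record` objects.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_mgf <- function(spectra, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in spectra) {
    writeLines(c("BEGIN IONS",
                 paste0("TITLE=", s$spectrum_id),
                 sprintf("PEPMASS=%.5f", s$precursor_mz),
                 sprintf("CHARGE=%d+", s$charge),
                 sprintf("%.5f %.1f", s$mz, s$intensity),
                 "END IONS"), con)
  }
  invisible(path)
}

#' Write a labelled square matrix as TSV
#'
#' First row and first column carry the labels; values are formatted with six
#' significant digits so a write/read round trip agrees within 1e-6.
#'
#' @param m square numeric matrix with identical, unique row/column names.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_matrix <- function(m, path) {
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    stop2("matrix must be square")
  }
  labels <- rownames(m)
  if (is.null(labels) || is.null(colnames(m)) ||
      !identical(labels, colnames(m)) || anyDuplicated(labels)) {
    stop2("matrix must carry identical, unique row and column labels")
  }
  lines <- c(paste(c("", labels), collapse = "\t"),
             vapply(seq_len(nrow(m)), function(i) {
               paste(c(labels[i], formatC(m[i, ], format = "g", digits = 6)),
                     collapse = "\t")
             }, ""))
  writeLines(lines, path)
  invisible(path)
}

#' Read a labelled square matrix from TSV
#'
#' @param path path written by [write_matrix()].
#' @return a labelled square numeric matrix.
#' @export
read_matrix <- function(path) {
  if (!file.exists(path)) stop2("no such file: ", path)
  raw <- utils::read.delim(path, row.names = 1, check.names = FALSE)
  m <- as.matrix(raw)
  if (nrow(m) != ncol(m) || !identical(rownames(m), colnames(m))) {
    stop2("file does not contain a labelled square matrix: ", path)
  }
  m
}
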