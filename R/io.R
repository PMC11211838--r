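#' Read sequences from a FASTA file
#'
#' Standard multi-record FASTA (wrapped or unwrapped lines). Record ids are
#' the header token up to the first whitespace; residues are uppercased and
#' alignment gap characters (`-`, `.`) are stripped, since queries and
#' backbone members are handled unaligned. Duplicate ids and empty sequences
#' are rejected.
#'
#' @param path Path to a FASTA file.
#' @return Named character vector of sequences.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) jb_data_error(sprintf("FASTA file not found: %s", path))
  set <- tryCatch(
    Biostrings::readBStringSet(path),
    error = function(e) jb_data_error(sprintf("cannot parse FASTA '%s': %s",
                                              path, conditionMessage(e)))
  )
  if (!length(set)) jb_data_error(sprintf("FASTA file '%s' contains no records", path))
  ids <- sub("\\s.*$", "", names(set))
  if (any(!nzchar(ids))) jb_data_error(sprintf("empty record id in '%s'", path))
  if (anyDuplicated(ids)) {
    jb_data_error(sprintf("duplicate record id(s) in '%s': %s", path,
                          paste(unique(ids[duplicated(ids)]), collapse = ", ")))
  }
  seqs <- toupper(as.character(set))
  seqs <- gsub("[-.]", "", seqs)
  if (any(!nzchar(seqs))) {
    jb_data_error(sprintf("empty sequence(s) in '%s': %s", path,
                          paste(ids[!nzchar(seqs)], collapse = ", ")))
  }
  stats::setNames(unname(seqs), ids)
}

#' Write sequences to a FASTA file
#'
#' @param x Named character vector of sequences.
#' @param path Output path.
#' @param width Line-wrap width for residues.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(x, path, width = 60L) {
  if (is.null(names(x)) || any(!nzchar(names(x)))) {
    jb_invalid_input("sequences must be named")
  }
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(x)) {
    writeLines(paste0(">", names(x)[i]), con)
    s <- x[[i]]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Read a family manifest
#'
#' A manifest is a TSV with header columns `family_id` and `fasta_path`
#' (paths resolved relative to the manifest's directory), one row per family.
#' An optional comment line `#root=<id>` designates the root (fallback)
#' family; other `#` lines are ignored.
#'
#' @param path Path to the manifest TSV.
#' @return A `family_manifest`: list with `entries` (data.frame `family_id`,
#'   `fasta_path`, absolute paths) and `root_id` (`NA` if not designated).
#' @export
read_manifest <- function(path) {
  if (!file.exists(path)) jb_data_error(sprintf("manifest not found: %s", path))
  lines <- readLines(path, warn = FALSE)
  root_id <- NA_character_
  root_lines <- grep("^#root=", lines, value = TRUE)
  if (length(root_lines)) root_id <- sub("^#root=", "", root_lines[[1L]])
  body <- lines[!startsWith(lines, "#")]
  body <- body[nzchar(trimws(body))]
  if (!length(body)) jb_data_error(sprintf("manifest '%s' has no entries", path))
  df <- tryCatch(
    utils::read.table(text = body, sep = "\t", header = TRUE,
                      stringsAsFactors = FALSE, comment.char = ""),
    error = function(e) jb_data_error(sprintf("cannot parse manifest '%s': %s",
                                              path, conditionMessage(e)))
  )
  if (!all(c("family_id", "fasta_path") %in% names(df))) {
    jb_data_error(sprintf(
      "manifest '%s' must have columns 'family_id' and 'fasta_path'", path))
  }
  if (anyDuplicated(df$family_id)) {
    jb_data_error(sprintf("duplicate family id(s) in manifest '%s': %s", path,
                          paste(unique(df$family_id[duplicated(df$family_id)]),
                                collapse = ", ")))
  }
  base <- dirname(normalizePath(path))
  resolved <- ifelse(grepl("^(/|[A-Za-z]:)", df$fasta_path), df$fasta_path,
                     file.path(base, df$fasta_path))
  missing <- !file.exists(resolved)
  if (any(missing)) {
    jb_data_error(sprintf("manifest '%s' references missing file(s): %s", path,
                          paste(df$fasta_path[missing], collapse = ", ")))
  }
  if (!is.na(root_id) && !(root_id %in% df$family_id)) {
    jb_data_error(sprintf("manifest root '%s' is not among the family ids", root_id))
  }
  structure(list(entries = data.frame(family_id = df$family_id,
                                      fasta_path = resolved,
                                      stringsAsFactors = FALSE),
                 root_id = root_id),
            class = "family_manifest")
}

#' Load the member sequences of every family in a manifest
#'
#' @param manifest A `family_manifest` from [read_manifest()].
#' @return Named list: family id -> character vector of member sequences.
#' @export
load_families <- function(manifest) {
  stopifnot(inherits(manifest, "family_manifest"))
  fams <- lapply(manifest$entries$fasta_path, read_fasta)
  stats::setNames(fams, manifest$entries$family_id)
}

#' @export
print.family_manifest <- function(x, ...) {
  cat(sprintf("<family_manifest> %d families, root=%s\n",
              nrow(x$entries),
              if (is.na(x$root_id)) "<unset>" else x$root_id))
  invisible(x)
}
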