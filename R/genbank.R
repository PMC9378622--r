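#' Write a construct as a GenBank flat file
#'
#' Minimal LOCUS/FEATURES/ORIGIN flat file with one \code{misc_feature} per
#' provenance segment, tag and restriction site. Internal coordinates are
#' 0-based half-open; serialization follows the GenBank convention of
#' 1-based inclusive, i.e. exactly +1 is added to each start. The LOCUS date
#' is fixed so that output is byte-identical across runs.
#'
#' @param construct A \code{ConstructRecord}.
#' @param path Output path.
#' @param comment Optional COMMENT lines (e.g. vector/promoter metadata,
#'   config hash, seed).
#' @return Invisibly, \code{path}.
#' @export
write_genbank <- function(construct, path, comment = character(0)) {
  validate_construct(construct)
  dna <- tolower(construct$dna)
  n <- nchar(dna)
  lines <- c(sprintf("LOCUS       %-16s %11d bp    DNA     linear   SYN 01-JAN-1980",
                     substr(gsub("\\s", "_", construct$name), 1, 16), n),
             sprintf("DEFINITION  %s chimeric GPCR construct.", construct$name))
  for (cm in comment) lines <- c(lines, sprintf("COMMENT     %s", cm))
  lines <- c(lines, "FEATURES             Location/Qualifiers")
  feats <- construct$features
  for (i in seq_len(NROW(feats))) {
    lines <- c(lines,
               sprintf("     misc_feature    %d..%d",
                       feats$start[i] + 1L, feats$end[i]),
               sprintf("                     /label=\"%s\"", feats$label[i]),
               sprintf("                     /note=\"origin:%s\"",
                       feats$origin[i]))
  }
  lines <- c(lines, "ORIGIN")
  for (s in seq(1L, n, by = 60L)) {
    chunk <- substring(dna, s, min(s + 59L, n))
    blocks <- substring(chunk, seq(1L, nchar(chunk), by = 10L),
                        pmin(seq(10L, nchar(chunk) + 9L, by = 10L),
                             nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", s, paste(blocks, collapse = " ")))
  }
  lines <- c(lines, "//")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(lines, con, sep = "\n")
  invisible(path)
}

#' Parse features and sequence back out of a GenBank flat file
#'
#' Round-trip companion to [write_genbank()]; reads the subset of the format
#' that the writer emits (misc_feature with label and origin note).
#'
#' @param path GenBank file path.
#' @return List with \code{name}, \code{dna} (uppercase) and \code{features}
#'   (data.frame, 0-based half-open coordinates).
#' @export
read_genbank <- function(path) {
  lines <- readLines(path)
  name <- sub("^LOCUS\\s+(\\S+).*", "\\1", lines[grepl("^LOCUS", lines)][1])
  fidx <- grep("^     misc_feature", lines)
  feats <- lapply(fidx, function(i) {
    loc <- sub("^\\s*misc_feature\\s+", "", lines[i])
    parts <- as.integer(strsplit(loc, "..", fixed = TRUE)[[1]])
    lab <- sub('.*?/label="([^"]*)".*', "\\1", lines[i + 1L])
    org <- sub('.*?/note="origin:([^"]*)".*', "\\1", lines[i + 2L])
    data.frame(label = lab, origin = org, start = parts[1L] - 1L,
               end = parts[2L], stringsAsFactors = FALSE)
  })
  o <- grep("^ORIGIN", lines)
  end <- grep("^//", lines)
  seq_lines <- lines[(o + 1L):(end - 1L)]
  dna <- toupper(gsub("[^a-zA-Z]", "", paste(seq_lines, collapse = "")))
  list(name = name,
       dna = dna,
       features = if (length(feats) > 0L) do.call(rbind, feats) else
         data.frame(label = character(0), origin = character(0),
                    start = integer(0), end = integer(0)))
}
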