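#' Write a plasmid record as a GenBank flat file
#'
#' Minimal GenBank writer: LOCUS line (length, DNA, circular/linear),
#' FEATURES block with a `source` feature and one `CDS` per ORF
#' (`complement(a..b)` for minus-strand features, `join(a..L,1..b)` for
#' origin-spanning features on circular records), and the ORIGIN sequence
#' block.
#'
#' @param record a [PlasmidRecord-class].
#' @param path output file path.
#' @return invisibly, the path.
#' @export
writeGenBank <- function(record, path) {
  seq <- tolower(as.character(plasmidSequence(record)))
  len <- nchar(seq)
  topo <- if (record@circular) "circular" else "linear"
  lines <- sprintf("LOCUS       %-16s %d bp    DNA     %s   UNC",
                   record@name, as.integer(len), topo)
  lines <- c(lines,
             paste0("DEFINITION  ", record@name, "."),
             "FEATURES             Location/Qualifiers",
             sprintf("     source          1..%d", len))
  f <- orfFeatures(record)
  for (i in seq_len(nrow(f))) {
    loc <- if (f$end[i] <= len) {
      sprintf("%d..%d", f$start[i], f$end[i])
    } else {
      sprintf("join(%d..%d,1..%d)", f$start[i], len, f$end[i] - len)
    }
    if (f$strand[i] == "-") loc <- sprintf("complement(%s)", loc)
    lines <- c(lines,
               sprintf("     CDS             %s", loc),
               sprintf("                     /locus_tag=\"%s\"", f$id[i]))
  }
  lines <- c(lines, "ORIGIN")
  starts <- seq(1, len, 60)
  for (s in starts) {
    chunk <- substr(seq, s, min(s + 59, len))
    tens <- substring(chunk, seq(1, nchar(chunk), 10),
                      pmin(seq(10, nchar(chunk) + 9, 10), nchar(chunk)))
    lines <- c(lines, sprintf("%9d %s", s, paste(tens, collapse = " ")))
  }
  lines <- c(lines, "//")
  writeLines(lines, path)
  invisible(path)
}

## Parse one GenBank location string into (start, end, strand); `join` of
## two segments across the origin becomes an end coordinate beyond the
## record length (the wrap convention used by PlasmidRecord).
parseGenBankLocation <- function(loc, seqLength, id) {
  strand <- "+"
  loc <- gsub("[<>]", "", loc)
  if (grepl("^complement\\(", loc)) {
    strand <- "-"
    loc <- sub("^complement\\((.*)\\)$", "\\1", loc)
  }
  if (grepl("^join\\(", loc)) {
    inner <- sub("^join\\((.*)\\)$", "\\1", loc)
    parts <- strsplit(inner, ",", fixed = TRUE)[[1]]
    stopIfNot(length(parts) == 2,
              "feature '", id, "': only two-segment joins are supported")
    seg <- lapply(parts, function(p)
      as.integer(strsplit(p, "..", fixed = TRUE)[[1]]))
    stopIfNot(seg[[1]][2] == seqLength && seg[[2]][1] == 1,
              "feature '", id, "': join does not span the origin")
    return(list(start = seg[[1]][1], end = seqLength + seg[[2]][2],
                strand = strand))
  }
  bounds <- as.integer(strsplit(loc, "..", fixed = TRUE)[[1]])
  stopIfNot(length(bounds) == 2 && !anyNA(bounds),
            "feature '", id, "': unparseable location '", loc, "'")
  list(start = bounds[1], end = bounds[2], strand = strand)
}

#' Read a GenBank flat file into a plasmid record
#'
#' Minimal GenBank reader for annotated replicons: record name, length and
#' topology from the LOCUS line, CDS features (plain, `complement()` and
#' two-segment origin-spanning `join()` locations; ids from `/locus_tag`,
#' `/gene` or `/label`, else numbered), and the ORIGIN sequence.
#'
#' @param path GenBank file path.
#' @return a [PlasmidRecord-class].
#' @export
readGenBank <- function(path) {
  lines <- readLines(path)
  locus <- grep("^LOCUS", lines, value = TRUE)
  stopIfNot(length(locus) >= 1, "no LOCUS line in ", path)
  toks <- strsplit(trimws(locus[1]), "[[:space:]]+")[[1]]
  name <- toks[2]
  circular <- any(grepl("circular", locus[1], ignore.case = TRUE))

  originAt <- grep("^ORIGIN", lines)
  stopIfNot(length(originAt) == 1, "expected one ORIGIN block in ", path)
  endAt <- grep("^//", lines)
  endAt <- endAt[endAt > originAt][1]
  seqLines <- lines[(originAt + 1):(endAt - 1)]
  seqStr <- toupper(gsub("[^A-Za-z]", "", paste(seqLines, collapse = "")))
  seqLength <- nchar(seqStr)

  ## collect CDS feature headers (and continuation lines of their location)
  featStart <- grep("^FEATURES", lines)
  feats <- list()
  if (length(featStart)) {
    block <- lines[(featStart + 1):(originAt - 1)]
    i <- 1
    n <- 0L
    while (i <= length(block)) {
      ln <- block[i]
      if (grepl("^     CDS\\s", ln)) {
        loc <- trimws(sub("^     CDS\\s+", "", ln))
        j <- i + 1
        while (j <= length(block) && grepl("^\\s{21}[^/]", block[j])) {
          loc <- paste0(loc, trimws(block[j]))
          j <- j + 1
        }
        ## scan qualifiers for an id until the next feature header
        id <- NA_character_
        while (j <= length(block) && grepl("^\\s{21}/", block[j])) {
          q <- trimws(block[j])
          m <- regmatches(q, regexec(
            "^/(locus_tag|gene|label)=\"?([^\"]+)\"?$", q))[[1]]
          if (length(m) == 3 && is.na(id)) id <- m[3]
          j <- j + 1
        }
        n <- n + 1L
        if (is.na(id)) id <- sprintf("cds_%03d", n)
        parsed <- parseGenBankLocation(loc, seqLength, id)
        feats[[n]] <- data.frame(id = id, start = parsed$start,
                                 end = parsed$end, strand = parsed$strand)
        i <- j
      } else {
        i <- i + 1
      }
    }
  }
  features <- if (length(feats)) do.call(rbind, feats) else
    data.frame(id = character(), start = integer(), end = integer(),
               strand = character())
  new("PlasmidRecord", name = name,
      sequence = Biostrings::DNAString(seqStr),
      circular = circular, features = features)
}

#' Write a plasmid record as FASTA
#'
#' @param record a [PlasmidRecord-class].
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeFasta <- function(record, path) {
  x <- Biostrings::DNAStringSet(plasmidSequence(record))
  names(x) <- record@name
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}
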