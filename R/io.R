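## Every output file starts with comment lines carrying the configuration
## hash and seed so a results table can always be matched to the run that
## produced it. No timestamps: outputs are byte-identical across reruns.
writeTableWithHeader <- function(df, path, header = character()) {
  con <- file(path, "w")
  on.exit(close(con))
  for (h in header) writeLines(paste0("# ", h), con)
  write.table(df, con, sep = ",", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a competition dataset as CSV
#'
#' Columns `plasmid`, `mutation`, `replicate`, the four observed count
#' columns, and (when `latent = TRUE`) the latent pre-sampling counts.
#'
#' @param assays a [CompetitionAssaySet-class] or compatible data.frame.
#' @param path output path.
#' @param latent include latent-count columns if present (default `TRUE`).
#' @param header extra comment lines for the file header.
#' @return invisibly, the path.
#' @export
writeCompetitionCsv <- function(assays, path, latent = TRUE,
                                header = character()) {
  rec <- if (is(assays, "CompetitionAssaySet")) records(assays) else assays
  if (!latent)
    rec <- rec[, !startsWith(names(rec), "latent_"), drop = FALSE]
  writeTableWithHeader(rec, path, header)
}

#' Read a competition dataset CSV
#'
#' Reads the dialect written by [writeCompetitionCsv()] (comment lines
#' starting with `#` are skipped) and validates it into an assay set.
#'
#' @param path CSV path.
#' @return a [CompetitionAssaySet-class].
#' @export
readCompetitionCsv <- function(path) {
  rec <- read.table(path, sep = ",", header = TRUE, comment.char = "#",
                    stringsAsFactors = FALSE)
  new("CompetitionAssaySet", records = rec, metadata = list(source = path))
}

#' Write depth profiles as a 3-column TSV
#'
#' Long format: `replicon`, `position` (1-based), `depth`.
#'
#' @param profiles list of [DepthProfile-class] objects.
#' @param path output path.
#' @return invisibly, the path.
#' @export
writeDepthTable <- function(profiles, path) {
  rows <- lapply(profiles, function(p)
    data.frame(replicon = replicon(p),
               position = seq_along(p@depth),
               depth = p@depth))
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  con <- file(path, "w")
  on.exit(close(con))
  write.table(df, con, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a depth TSV into depth profiles
#'
#' Expects columns `replicon`, `position`, `depth`; positions are 1-based
#' and must be complete per replicon.
#'
#' @param path TSV path.
#' @return named list of [DepthProfile-class] objects, one per replicon.
#' @export
readDepthTable <- function(path) {
  df <- read.table(path, sep = "\t", header = TRUE, comment.char = "#",
                   stringsAsFactors = FALSE)
  need <- c("replicon", "position", "depth")
  stopIfNot(all(need %in% names(df)),
            "depth table must have columns: ", paste(need, collapse = ", "))
  out <- lapply(split(df, df$replicon), function(d) {
    d <- d[order(d$position), ]
    stopIfNot(identical(as.integer(d$position), seq_len(nrow(d))),
              "positions of replicon '", d$replicon[1],
              "' are not 1..n")
    new("DepthProfile", replicon = d$replicon[1], depth = d$depth)
  })
  out
}

#' Read a pipeline configuration file
#'
#' YAML key-value file; see [runPipeline()] for the recognized keys.
#'
#' @param path YAML path.
#' @return named list.
#' @export
readPipelineConfig <- function(path) {
  cfg <- yaml::read_yaml(path)
  stopIfNot(is.list(cfg), "configuration must be a YAML mapping")
  cfg
}
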