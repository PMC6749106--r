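#' Write and read result tables with a metadata header
#'
#' CSV files carry a `#`-prefixed header block (tool version, seed, config
#' hash and any caller-supplied metadata) above the data; numeric columns
#' are serialized with 10 significant digits. JSON files wrap the same
#' metadata and data in one object. `read_results()` restores the table and
#' exposes the metadata as the `"metadata"` attribute.
#'
#' @param x A data frame.
#' @param path Output path; format inferred from the extension (`.csv` or
#'   `.json`) unless `format` is given.
#' @param format `"csv"` or `"json"`.
#' @param meta Named list of metadata values (e.g. `list(seed = 42)`).
#' @return `write_results()` returns `path` invisibly; `read_results()`
#'   returns a tibble.
#' @examples
#' p <- tempfile(fileext = ".csv")
#' write_results(data.frame(x = 1:3), p, meta = list(seed = 1))
#' read_results(p)
#' @export
write_results <- function(x, path, format = NULL, meta = list()) {
  stopifnot(is.data.frame(x))
  format <- format %||% infer_format(path)
  meta <- c(list(tool = paste0("seqeffort ",
                               as.character(packageVersion("seqeffort"))),
                 config_hash = rlang::hash(list(names(x), meta))),
            meta)
  if (format == "csv") {
    df <- as.data.frame(x)
    for (j in seq_along(df)) {
      if (is.numeric(df[[j]])) {
        df[[j]] <- formatC(df[[j]], digits = 10, format = "g")
      }
    }
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(sprintf("# %s: %s", names(meta),
                       vapply(meta, function(v) base::format(v),
                              character(1))), con)
    utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  } else {
    jsonlite::write_json(list(metadata = meta, data = x), path,
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path, format = NULL) {
  format <- format %||% infer_format(path)
  if (format == "csv") {
    lines <- readLines(path)
    hdr <- grep("^#", lines, value = TRUE)
    meta <- list()
    for (h in hdr) {
      kv <- sub("^#\\s*", "", h)
      key <- sub(":.*$", "", kv)
      meta[[key]] <- sub("^[^:]*:\\s*", "", kv)
    }
    df <- utils::read.csv(text = lines[!grepl("^#", lines)])
    out <- tibble::as_tibble(df)
  } else {
    payload <- jsonlite::read_json(path, simplifyVector = TRUE)
    out <- tibble::as_tibble(payload$data)
    meta <- payload$metadata
  }
  attr(out, "metadata") <- meta
  out
}

infer_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("csv", "json")) ext else
    stop_domain(sprintf("cannot infer format from `%s`; pass `format`.",
                        path))
}

#' Serialize a community structure to JSON, and back
#'
#' Two spellings are accepted on read: an explicit group table
#' `{label, groups: [{size, mass}, ...]}` (what `write_community()` emits)
#' or a family spec `{family: "even"|"tiered"|"lognormal", ...params}`
#' that is rebuilt through the matching constructor.
#'
#' @param community A [community_structure()].
#' @param path JSON file path.
#' @return `write_community()` returns `path` invisibly; `read_community()`
#'   a [community_structure()].
#' @export
write_community <- function(community, path) {
  stopifnot(inherits(community, "community_structure"))
  payload <- list(label = community_label(community),
                  groups = data.frame(size = community$size,
                                      mass = community$mass))
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}

#' @rdname write_community
#' @export
read_community <- function(path) {
  payload <- jsonlite::read_json(path, simplifyVector = TRUE)
  community_from_spec(payload)
}

# build a community from a parsed JSON spec (group table or family form)
community_from_spec <- function(spec) {
  if (!is.null(spec$groups)) {
    return(community_structure(size = spec$groups$size,
                               mass = spec$groups$mass,
                               label = spec$label %||% "community"))
  }
  if (is.null(spec$family)) {
    stop_domain("community spec needs either `groups` or `family`.")
  }
  total <- spec$total_kmers %||%
    stop_domain("community family spec needs `total_kmers`.")
  switch(spec$family,
    even = community_even(total, label = spec$label %||% "even"),
    tiered = community_tiered(total,
                              mass_fraction = spec$mass_fraction %||% 0.9,
                              kmer_fraction = spec$kmer_fraction %||% 0.5),
    lognormal = community_lognormal(total, a = spec$a %||% 0.2,
                                    s0 = spec$s0 %||% 1,
                                    octaves = spec$octaves %||% 10,
                                    exponent = spec$exponent %||% "a_squared"),
    stop_domain(sprintf("unknown community family `%s`.", spec$family)))
}

#' Export a rank-abundance profile as CSV
#'
#' @param community A [community_structure()].
#' @param path CSV path.
#' @return `path`, invisibly.
#' @export
write_rank_abundance <- function(community, path) {
  write_results(rank_abundance(community), path,
                meta = list(label = community_label(community),
                            kmg_size = community_size(community)))
}
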