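# Trait-table and metadata CSV I/O (RFC-4180, UTF-8, "NA" for missing).

#' Read a per-image metadata table
#'
#' The first column is taken as the image identifier (renamed `image_id`);
#' all values are kept as strings. Duplicated identifiers keep the last
#' occurrence, with a warning.
#'
#' @param path CSV file with a header row.
#' @return a tibble with one row per image.
#' @export
read_metadata_csv <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("metadata file does not exist: ", path),
          class = "rootcrown_format_error")
  }
  tab <- tryCatch(
    readr::read_csv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE, show_col_types = FALSE),
    error = function(e) {
      abort(paste0("cannot parse metadata CSV: ", path),
            class = "rootcrown_format_error")
    }
  )
  if (ncol(tab) < 1 ||
      length(readr::read_lines(path, n_max = 1, progress = FALSE)) < 1) {
    abort(paste0("metadata CSV has no header: ", path),
          class = "rootcrown_format_error")
  }
  names(tab)[1] <- "image_id"
  if (anyDuplicated(tab$image_id)) {
    dup <- unique(tab$image_id[duplicated(tab$image_id)])
    warn(paste0("duplicate image ids in metadata (last occurrence kept): ",
                paste(dup, collapse = ", ")))
    tab <- tab[!duplicated(tab$image_id, fromLast = TRUE), , drop = FALSE]
  }
  as_tibble(tab)
}

#' Write computed traits as an Excel-compatible CSV
#'
#' One row per image; columns are `image_id`, the trait ids in registry
#' order, then any metadata columns. Traits that were not computed
#' (not-applicable or failed) are written as the literal string `NA`.
#'
#' @param records a single trait record or a list of them
#'   (see [compute_all()]).
#' @param registry trait registry tibble; defaults to [trait_registry()].
#' @param metadata optional tibble from [read_metadata_csv()], joined on
#'   `image_id`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_traits_csv <- function(records, registry = trait_registry(),
                             metadata = NULL, path) {
  if (inherits(records, "trait_record")) records <- list(records)
  ids <- registry$trait
  rows <- lapply(records, function(rec) {
    unknown <- setdiff(rec$trait, ids)
    if (length(unknown) > 0) {
      abort(paste0("trait record contains ids not in the registry: ",
                   paste(unknown, collapse = ", ")),
            class = "rootcrown_consistency_error")
    }
    vals <- setNames(rec$value, rec$trait)
    vals[rec$status != "ok"] <- NA_real_
    out <- as.list(vals[ids])
    names(out) <- ids
    c(list(image_id = attr(rec, "image_id") %||% "image"),
      out,
      list(units = attr(rec, "units") %||% "mm"))
  })
  tab <- if (length(rows) == 0) {
    cols <- c(list(image_id = character(0)),
              setNames(rep(list(double(0)), length(ids)), ids),
              list(units = character(0)))
    as_tibble(cols)
  } else {
    dplyr::bind_rows(lapply(rows, as_tibble))
  }
  if (!is.null(metadata)) {
    tab <- dplyr::left_join(tab, metadata, by = "image_id")
  }
  readr::write_csv(tab, path, na = "NA", progress = FALSE)
  invisible(path)
}
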