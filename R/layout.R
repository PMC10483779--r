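#' Microbioreactor plate layouts
#'
#' A plate layout assigns every well of a (default 48-well, 6 rows x 8
#' columns) microtiter plate to a cultivation group, a medium, and a
#' transfer role. Groups are rows by default, each hosting one independent
#' repetitive-batch run along its wells. Roles encode the transfer
#' topology: `"chain"` wells are inoculated from the previous well of the
#' same group (wrapping around under well recycling); `"branch_of_<G>"`
#' wells are inoculated from the concurrently triggering batch of chain
#' group `<G>` (fan-out layouts used to verify strains on a second carbon
#' source).
#'
#' @param n_rows,n_cols Plate dimensions (default 6 x 8).
#' @param media Medium label, either one string for all wells or a named
#'   vector by group.
#' @param groups Optional group label per row; defaults to row letters.
#'
#' @return A tibble with columns `well`, `group`, `medium`, `role` and class
#'   `rbale_layout`.
#' @examples
#' plate_layout()
#' plate_layout_fanout()
#' @export
plate_layout <- function(n_rows = 6, n_cols = 8, media = "glucose_111mM",
                         groups = LETTERS[seq_len(n_rows)]) {
  stopifnot(n_rows >= 1, n_cols >= 1, length(groups) == n_rows)
  rows <- LETTERS[seq_len(n_rows)]
  wells <- as.vector(t(outer(rows, seq_len(n_cols), paste0)))
  grp <- rep(groups, each = n_cols)
  med <- if (length(media) == 1L && is.null(names(media))) {
    rep(media, length(wells))
  } else {
    unname(media[grp])
  }
  out <- tibble::tibble(well = wells, group = grp, medium = med, role = "chain")
  class(out) <- c("rbale_layout", class(out))
  out
}

#' @describeIn plate_layout Alternating fan-out layout: odd rows are chains
#'   on glucose, even rows are branches on ethanol fed by the chain row
#'   above, so every ethanol batch is inoculated from the concurrent glucose
#'   batch and never from a previous ethanol batch.
#' @export
plate_layout_fanout <- function(n_rows = 6, n_cols = 8) {
  stopifnot(n_rows %% 2 == 0)
  lay <- plate_layout(n_rows, n_cols)
  rows <- LETTERS[seq_len(n_rows)]
  odd <- rows[seq(1, n_rows, by = 2)]
  lay$medium <- ifelse(lay$group %in% odd, "glucose_55mM", "ethanol_428mM")
  feeder <- stats::setNames(rep(odd, each = 2), rows)
  lay$role <- ifelse(lay$group %in% odd, "chain",
                     paste0("branch_of_", feeder[lay$group]))
  lay
}

#' Read and write plate-layout tables
#'
#' The external layout dialect is a CSV with columns
#' `well,group,medium,role`.
#'
#' @param layout A layout tibble.
#' @param path File path.
#' @return `read_layout()` returns a layout tibble; `write_layout()` returns
#'   `path` invisibly.
#' @export
write_layout <- function(layout, path) {
  readr::write_csv(layout[, c("well", "group", "medium", "role")], path)
  invisible(path)
}

#' @rdname write_layout
#' @export
read_layout <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    well = readr::col_character(), group = readr::col_character(),
    medium = readr::col_character(), role = readr::col_character()))
  class(out) <- c("rbale_layout", class(out))
  out
}

# group -> feeder group for branch groups, NA for chains
layout_feeders <- function(layout) {
  per_group <- layout[!duplicated(layout$group), c("group", "role")]
  feeder <- ifelse(grepl("^branch_of_", per_group$role),
                   sub("^branch_of_", "", per_group$role), NA_character_)
  stats::setNames(feeder, per_group$group)
}
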