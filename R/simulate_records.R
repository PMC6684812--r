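#' Simulate georeferenced fire records over an anthrome grid
#'
#' For each anthrome group, draws daily counts from the group's
#' [simulation_spec()] (respecting its `count_mode`: Poisson draws with
#' mean `exp(y_t)`, or deterministic `round(exp(y_t))`) and scatters that
#' many detections uniformly over the grid cells belonging to the group.
#' Records carry the acquisition date, a random time of day, alternating
#' Terra/Aqua satellite flags, confidence 100 and type 0, and round-trip
#' exactly through [write_mcd14ml()], [read_mcd14ml()] and
#' [assign_anthromes()].
#'
#' @param per_class_specs named list mapping anthrome group name to a
#'   [simulation_spec()]; all specs must share `n_days` and `start_date`.
#' @param grid an [anthrome_grid()]; every group in `per_class_specs` must
#'   occupy at least one cell.
#' @param seed integer seed.
#' @param mapping code-to-group mapping used to locate each group's cells.
#' @return A [fire_records()] data frame.
#' @export
simulate_fire_records <- function(per_class_specs, grid, seed = 1L,
                                  mapping = default_anthrome_mapping()) {
  stopifnot(inherits(grid, "anthrome_grid"))
  if (is.null(names(per_class_specs)) || any(!nzchar(names(per_class_specs))))
    stop("'per_class_specs' must be a named list (group -> spec)")
  cell_group <- matrix(NA_character_, grid$nrows, grid$ncols)
  known <- as.integer(names(mapping))
  idx <- match(as.vector(grid$codes), known)
  cell_group[] <- ifelse(is.na(idx), NA_character_, unname(mapping[idx]))
  cell_group[grid$codes == grid$nodata] <- NA_character_

  set.seed(seed)
  ytop <- grid$yllcorner + grid$nrows * grid$cellsize
  pieces <- vector("list", length(per_class_specs))
  for (g in seq_along(per_class_specs)) {
    group <- names(per_class_specs)[g]
    spec <- per_class_specs[[group]]
    stopifnot(inherits(spec, "simulation_spec"))
    cells <- which(cell_group == group)  # column-major indices
    if (length(cells) == 0)
      stop("group '", group, "' occupies no grid cell")
    sub_seed <- sample.int(.Machine$integer.max, 1L)
    counts <- simulate_count_series(spec, seed = sub_seed)$counts
    total <- sum(counts)
    if (total == 0) next
    # restore the outer stream after the nested, separately seeded draw
    set.seed(seed + g)
    day_of <- rep(seq_along(counts), counts)
    pick <- cells[sample.int(length(cells), total, replace = TRUE)]
    row <- (pick - 1L) %% grid$nrows + 1L
    col <- (pick - 1L) %/% grid$nrows + 1L
    lon <- grid$xllcorner + (col - 1 + stats::runif(total)) * grid$cellsize
    lat <- ytop - (row - 1 + stats::runif(total)) * grid$cellsize
    pieces[[g]] <- data.frame(
      acq_date = spec$start_date + (day_of - 1),
      acq_time = sample.int(1440L, total, replace = TRUE) - 1L,
      satellite = c("T", "A")[(seq_len(total) %% 2L) + 1L],
      lat = lat, lon = lon,
      confidence = 100L, type = 0L,
      stringsAsFactors = FALSE)
  }
  pieces <- pieces[!vapply(pieces, is.null, logical(1))]
  if (length(pieces) == 0) return(empty_fire_records())
  df <- do.call(rbind, pieces)
  df <- df[order(df$acq_date, df$acq_time), , drop = FALSE]
  fire_records(df$acq_date, df$acq_time, df$satellite, df$lat, df$lon,
               df$confidence, df$type)
}
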