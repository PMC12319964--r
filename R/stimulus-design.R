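#' Per-frequency contrast sampling grid
#'
#' Twelve contrasts for one stimulus block, placed where they sample the CSF
#' efficiently at that spatial frequency. The default rule puts `n` log-spaced
#' values between a per-frequency lower bound and 80% Michelson contrast; the
#' lower bound sits a fixed log-distance (factor `lower_divisor`) below the
#' standard reference CSF's threshold contrast at that frequency, and is never
#' allowed below 0.25%. At high spatial frequencies the threshold is high, so
#' the grid starts higher — low contrasts that nobody can see are not wasted.
#'
#' @param sf Spatial frequency in cycles/degree (> 0).
#' @param n Number of contrasts per block (default 12).
#' @param range Allowed contrast range in percent (default `c(0.25, 80)`).
#' @param reference CSF anchoring the lower bound, default [standard_csf()].
#' @param lower_divisor The lower bound is `threshold(sf) / lower_divisor`
#'   (default 4), clipped into `range`.
#' @return Strictly increasing numeric vector of `n` contrasts in percent,
#'   with attribute `clipped = TRUE` if the rule had to be clipped into
#'   `range`.
#' @examples
#' contrast_grid(18) # starts well above 0.25%
#' contrast_grid(0.5) # starts at the 0.25% floor
#' @export
contrast_grid <- function(sf, n = 12, range = c(0.25, 80),
                          reference = standard_csf(), lower_divisor = 4) {
  stop_not_positive(sf, "sf")
  threshold <- 100 / csf_sensitivity(reference, sf)
  lo_raw <- threshold / lower_divisor
  clipped <- lo_raw < range[1] || lo_raw >= range[2]
  lo <- min(max(lo_raw, range[1]), range[2] / 2)
  out <- logspace(lo, range[2], n)
  if (clipped) attr(out, "clipped") <- TRUE
  out
}

#' Build the block-design stimulus protocol
#'
#' Generates the per-volume stimulus sequence of the grating protocol: for
#' each spatial frequency one block of ascending and one of descending
#' contrast (one contrast level per volume), pairs of stimulus blocks
#' separated by mean-luminance blanks, and a final blank. With the defaults
#' (TR 1.5 s, six spatial frequencies, 18 s blocks, 15 s blanks) this yields
#' 12 stimulus blocks of 12 volumes, 7 blank blocks of 10 volumes — 214
#' volumes, 321 s. Block order is a deterministic permutation drawn from
#' `order_seed` and recorded in the design metadata, so the protocol is fully
#' reproducible without hard-coding one particular ordering.
#'
#' @param tr Repetition time in seconds (default 1.5). Must divide both block
#'   durations exactly.
#' @param sf_set Spatial frequencies in cycles/degree
#'   (default `c(0.5, 1, 3, 6, 12, 18)`).
#' @param block_s Stimulus block duration in seconds (default 18).
#' @param blank_s Mean-luminance block duration in seconds (default 15).
#' @param contrasts Optional named list of per-frequency contrast vectors
#'   (names = spatial frequencies); defaults to [contrast_grid()] per
#'   frequency with `n = block_s / tr` levels.
#' @param order_seed Integer seed for the block-order permutation (default 42).
#' @return A tibble of class `ncsf_design` with columns `volume` (0-based),
#'   `onset_s`, `sf_cpd`, `contrast_pct` (0 for blanks), `block` (0 for
#'   blanks) and `direction` (`"ascending"`, `"descending"`, `"blank"`).
#'   Attributes: `tr`, `sf_set`, `order_seed`, `block_order`, `grid_rule`.
#' @examples
#' d <- build_design()
#' nrow(d) # 214 volumes
#' max(d$onset_s) + attr(d, "tr") # 321 s
#' @export
build_design <- function(tr = 1.5, sf_set = c(0.5, 1, 3, 6, 12, 18),
                         block_s = 18, blank_s = 15, contrasts = NULL,
                         order_seed = 42) {
  stop_not_positive(tr, "tr")
  n_block <- block_s / tr
  n_blank <- blank_s / tr
  if (abs(n_block - round(n_block)) > 1e-9 || abs(n_blank - round(n_blank)) > 1e-9) {
    abort("`tr` must divide both `block_s` and `blank_s` into whole volumes.")
  }
  n_block <- as.integer(round(n_block))
  n_blank <- as.integer(round(n_blank))
  clipped_sfs <- numeric(0)
  if (is.null(contrasts)) {
    contrasts <- lapply(sf_set, contrast_grid, n = n_block)
    names(contrasts) <- as.character(sf_set)
    clipped_sfs <- sf_set[vapply(contrasts, function(g) isTRUE(attr(g, "clipped")), logical(1))]
  }
  if (!setequal(names(contrasts), as.character(sf_set))) {
    abort("`contrasts` must be named by the spatial frequencies in `sf_set`.")
  }

  blocks <- tidyr::expand_grid(
    sf = sf_set, direction = c("ascending", "descending")
  )
  perm <- with_seed(order_seed, sample.int(nrow(blocks)))
  blocks <- blocks[perm, ]
  blocks$block <- seq_len(nrow(blocks))

  blank_row <- function() tibble::tibble(
    sf_cpd = rep(0, n_blank), contrast_pct = 0, block = 0L, direction = "blank"
  )
  stim_rows <- function(i) {
    grid <- contrasts[[as.character(blocks$sf[i])]]
    if (length(grid) != n_block) {
      abort(sprintf("contrast grid for sf = %g has %d values; block holds %d volumes",
                    blocks$sf[i], length(grid), n_block))
    }
    cv <- if (blocks$direction[i] == "ascending") sort(grid) else rev(sort(grid))
    tibble::tibble(sf_cpd = blocks$sf[i], contrast_pct = cv,
                   block = blocks$block[i], direction = blocks$direction[i])
  }

  pieces <- list()
  for (i in seq_len(nrow(blocks))) {
    if (i %% 2L == 1L) pieces[[length(pieces) + 1L]] <- blank_row()
    pieces[[length(pieces) + 1L]] <- stim_rows(i)
  }
  pieces[[length(pieces) + 1L]] <- blank_row()
  out <- dplyr::bind_rows(pieces)
  out <- dplyr::mutate(out,
    volume = dplyr::row_number() - 1L,
    onset_s = .data$volume * tr,
    .before = 1L
  )
  design <- new_ncsf_design(out, tr = tr, sf_set = sf_set, order_seed = order_seed,
                            block_order = blocks[c("block", "sf", "direction")],
                            grid_rule = "log-spaced from max(0.25, standard-threshold/4) to 80%")
  attr(design, "clipped_sfs") <- clipped_sfs
  design
}

new_ncsf_design <- function(df, tr, sf_set, order_seed = NA_integer_,
                            block_order = NULL, grid_rule = NA_character_) {
  structure(
    tibble::as_tibble(df),
    tr = tr, sf_set = sf_set, order_seed = order_seed,
    block_order = block_order, grid_rule = grid_rule,
    class = c("ncsf_design", class(tibble::tibble()))
  )
}

#' Summarize the block structure of a design
#'
#' Scans a per-volume design for contiguous runs of the same block label and
#' reports one row per stimulus block: its spatial frequency, direction,
#' length in volumes, and the number of distinct contrasts shown.
#'
#' @param design An `ncsf_design` (or any data frame with `sf_cpd`,
#'   `contrast_pct`, `block` columns).
#' @return A tibble with one row per stimulus block.
#' @export
design_blocks <- function(design) {
  design |>
    dplyr::filter(.data$block > 0) |>
    dplyr::group_by(.data$block) |>
    dplyr::summarise(
      sf_cpd = .data$sf_cpd[1],
      direction = .data$direction[1],
      n_volumes = dplyr::n(),
      n_contrasts = dplyr::n_distinct(.data$contrast_pct),
      .groups = "drop"
    )
}

#' Write and read stimulus designs
#'
#' Designs are serialized as tab-separated text with columns `volume`,
#' `sf_cpd`, `contrast_pct`, `block`, `direction`, plus a JSON sidecar
#' (`<path>.json`) holding the repetition time, the spatial-frequency set,
#' the ordering seed and the grid rule. `read_design()` restores the sidecar
#' metadata when present and validates the rows: contrasts must be
#' nonnegative, and a zero contrast must coincide with a zero spatial
#' frequency (a blank). Write-then-read is an exact round trip.
#'
#' @param design An `ncsf_design`.
#' @param path File path for the TSV (sidecar written next to it).
#' @param tr Repetition time to assume when no sidecar exists (default 1.5).
#' @return `write_design()` returns `path` invisibly; `read_design()` returns
#'   an `ncsf_design`.
#' @export
write_design <- function(design, path) {
  readr::write_tsv(
    design[c("volume", "sf_cpd", "contrast_pct", "block", "direction")], path
  )
  meta <- list(
    tr = attr(design, "tr"),
    sf_set = attr(design, "sf_set"),
    order_seed = attr(design, "order_seed"),
    grid_rule = attr(design, "grid_rule")
  )
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_design
#' @export
read_design <- function(path, tr = 1.5) {
  df <- readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
  required <- c("volume", "sf_cpd", "contrast_pct")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    abort(sprintf("design file is missing column(s): %s",
                  paste(missing, collapse = ", ")))
  }
  bad <- which(df$contrast_pct < 0)
  if (length(bad) > 0) {
    abort(sprintf("negative contrast at row %d of %s", bad[1], path))
  }
  bad <- which((df$contrast_pct == 0) != (df$sf_cpd == 0))
  if (length(bad) > 0) {
    abort(sprintf(
      "row %d of %s: contrast and spatial frequency must be zero together (blank)",
      bad[1], path
    ))
  }
  if (!"block" %in% names(df)) {
    # recover contiguous block labels from the stimulus/blank alternation;
    # adjacent blocks of the same frequency (ascending/descending pairs)
    # meet at a repeated contrast, since contrasts are distinct in a block
    is_stim <- df$contrast_pct > 0
    changes <- c(TRUE, diff(as.integer(is_stim)) != 0 |
                   diff(df$sf_cpd) != 0 |
                   (diff(df$contrast_pct) == 0 & is_stim[-1]))
    run_id <- cumsum(changes)
    stim_runs <- unique(run_id[is_stim])
    df$block <- ifelse(is_stim, match(run_id, stim_runs), 0L)
  }
  if (!"direction" %in% names(df)) {
    df$direction <- ifelse(df$block == 0L, "blank", NA_character_)
    for (b in setdiff(unique(df$block), 0L)) {
      cv <- df$contrast_pct[df$block == b]
      df$direction[df$block == b] <-
        if (cv[length(cv)] >= cv[1]) "ascending" else "descending"
    }
  }
  meta_path <- paste0(path, ".json")
  meta <- if (file.exists(meta_path)) jsonlite::read_json(meta_path, simplifyVector = TRUE) else list()
  if (!"onset_s" %in% names(df)) {
    df <- dplyr::mutate(df, onset_s = .data$volume * (meta$tr %||% tr),
                        .after = "volume")
  }
  new_ncsf_design(
    df,
    tr = meta$tr %||% tr,
    sf_set = meta$sf_set %||% sort(unique(df$sf_cpd[df$sf_cpd > 0])),
    order_seed = meta$order_seed %||% NA_integer_,
    grid_rule = meta$grid_rule %||% NA_character_
  )
}
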