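#' Read a stem census table
#'
#' Reads a forest inventory (one row per stem) from CSV or XLSX, validates it
#' and applies the census threshold: stems with DBH <= 10 cm are excluded
#' (with a message reporting how many). Required columns are `species` and
#' `dbh_cm`; optional columns `tree_id`, `height_m`, `crown_diameter_m`,
#' `x_m`, `y_m` are kept when present.
#'
#' @param path Path to the census file.
#' @param dialect `"csv"` or `"xlsx"`; guessed from the extension by default.
#' @param min_dbh_cm Census threshold in cm (default 10).
#' @return A tibble of validated census records (dbh in cm in column
#'   `dbh_cm`), with attribute `n_excluded`.
#' @export
read_census <- function(path, dialect = c("auto", "csv", "xlsx"),
                        min_dbh_cm = 10) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("no such file: ", path, call. = FALSE)
  if (dialect == "auto") {
    dialect <- if (tolower(tools::file_ext(path)) %in% c("xlsx", "xls"))
      "xlsx" else "csv"
  }
  raw <- if (dialect == "xlsx") {
    if (!requireNamespace("readxl", quietly = TRUE)) {
      stop("reading xlsx requires the readxl package", call. = FALSE)
    }
    readxl::read_excel(path)
  } else {
    readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  }
  validate_census(tibble::as_tibble(raw), min_dbh_cm = min_dbh_cm)
}

validate_census <- function(census, min_dbh_cm = 10) {
  required <- c("species", "dbh_cm")
  missing <- setdiff(required, names(census))
  if (length(missing) > 0) {
    stop("census is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  if (nrow(census) == 0) {
    warning("census file is empty (header only)", call. = FALSE)
    return(structure(census, n_excluded = 0L))
  }
  dbh <- suppressWarnings(as.numeric(census$dbh_cm))
  bad <- which(is.na(dbh))
  if (length(bad) > 0) {
    stop("non-numeric dbh_cm in row(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  census$dbh_cm <- dbh
  keep <- dbh > min_dbh_cm
  n_excluded <- sum(!keep)
  if (n_excluded > 0) {
    message(n_excluded, " stem(s) at or below the ", min_dbh_cm,
            " cm census threshold excluded")
  }
  for (col in c("x_m", "y_m")) {
    if (col %in% names(census) && any(stats::na.omit(census[[col]]) < 0)) {
      stop("negative plot coordinates in column ", col, call. = FALSE)
    }
  }
  structure(census[keep, , drop = FALSE], n_excluded = n_excluded)
}

#' Assign species to plant functional types from traits
#'
#' Maps every species to one of the PFTs defined by the cross of three
#' maximum-height classes (<16 m, 16-33 m, >33 m; half-open boundaries
#' \[0,16), \[16,33), \[33,Inf)) and three shade-tolerance classes. Shade
#' tolerance is scored from two functional traits: species are ranked on
#' \eqn{z(\mathrm{SDMC}) - z(\mathrm{leaf~N})} (high stem dry matter content
#' and low leaf nitrogen indicate shade tolerance) and the ranking is cut
#' into terciles (tolerant / intermediate / intolerant). An explicit
#' `light_class_override` column wins over the trait score.
#'
#' @param traits A data frame with columns `species`, `max_height_m`, `sdmc`
#'   (stem dry matter content, g/g), `leaf_n` (leaf nitrogen, mg/g) and
#'   optionally `light_class_override` (one of `"tolerant"`,
#'   `"intermediate"`, `"intolerant"`, or `NA`).
#' @param params PFT parameter table defining the (height class, light class)
#'   to PFT mapping.
#' @return A tibble `species, max_height_m, height_class, light_class, pft`.
#' @export
assign_pft <- function(traits, params = pft_parameters()) {
  required <- c("species", "max_height_m", "sdmc", "leaf_n")
  missing <- setdiff(required, names(traits))
  if (length(missing) > 0) {
    stop("traits table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  traits <- dplyr::arrange(tibble::as_tibble(traits), .data$species)
  if (any(traits$max_height_m <= 0)) {
    stop("max_height_m must be positive", call. = FALSE)
  }

  height_class <- cut(traits$max_height_m, breaks = c(0, 16, 33, Inf),
                      labels = c("<16", "16-33", ">33"), right = FALSE)

  score <- scale_z(traits$sdmc) - scale_z(traits$leaf_n)
  light_class <- tercile_class(score)
  if ("light_class_override" %in% names(traits)) {
    ov <- as.character(traits$light_class_override)
    valid <- ov %in% c("tolerant", "intermediate", "intolerant")
    light_class[valid] <- ov[valid]
  }

  key <- paste(params$height_class, params$light_class)
  pft <- params$pft[match(paste(as.character(height_class), light_class), key)]
  un <- is.na(pft)
  if (any(un)) {
    stop("no PFT defined for species (height class x light class not in the ",
         "parameter table): ",
         paste(traits$species[un], collapse = ", "), call. = FALSE)
  }
  tibble::tibble(species = traits$species,
                 max_height_m = traits$max_height_m,
                 height_class = as.character(height_class),
                 light_class = light_class,
                 pft = pft)
}

scale_z <- function(x) {
  s <- stats::sd(x)
  if (!is.finite(s) || s == 0) return(rep(0, length(x)))
  (x - mean(x)) / s
}

# rank-based terciles: top third of the shade-tolerance score -> tolerant
tercile_class <- function(score) {
  r <- rank(-score, ties.method = "first")  # 1 = most tolerant
  n <- length(score)
  cls <- character(n)
  cls[r <= ceiling(n / 3)] <- "tolerant"
  cls[r > ceiling(n / 3) & r <= ceiling(2 * n / 3)] <- "intermediate"
  cls[r > ceiling(2 * n / 3)] <- "intolerant"
  cls
}

#' Field statistics and calibration targets from a census
#'
#' Computes, per PFT and in total, the aboveground biomass (t_odm/ha), basal
#' area (m^2/ha) and stem density (ha^-1) of a census plot, plus the stem
#' size distribution in 10-cm DBH bins, linearly upscaled to one hectare
#' (factor 10000 / plot area; 4 for a 50 m x 50 m plot). Biomass uses the
#' same allometric assumptions as the simulator; measured heights, when
#' present, replace the allometric height.
#'
#' @param census A validated census tibble (see [read_census()]).
#' @param assignment Species-to-PFT mapping from [assign_pft()].
#' @param params PFT parameter table.
#' @param plot_area_m2 Inventory plot area in m^2 (default 2500).
#' @param bin_width_cm DBH bin width for the size distribution, cm.
#' @return A list of class `field_targets` with elements `by_pft` (tibble:
#'   `pft, agb, basal_area, stems`), `total` (one-row tibble) and
#'   `size_distribution` (tibble: `dbh_class, stems`), all per hectare.
#' @export
field_statistics <- function(census, assignment, params = pft_parameters(),
                             plot_area_m2 = 2500, bin_width_cm = 10) {
  if (plot_area_m2 <= 0) stop("plot area must be positive", call. = FALSE)
  up <- 10000 / plot_area_m2
  pfts <- sort(params$pft)

  if (nrow(census) == 0) {
    by_pft <- tibble::tibble(pft = pfts, agb = 0, basal_area = 0, stems = 0)
    total <- tibble::tibble(agb = 0, basal_area = 0, stems = 0)
    sd_tbl <- size_distribution_bins(numeric(0), bin_width_cm)
    return(structure(list(by_pft = by_pft, total = total,
                          size_distribution = sd_tbl,
                          upscaling_factor = up),
                     class = "field_targets"))
  }

  pft <- assignment$pft[match(census$species, assignment$species)]
  if (any(is.na(pft))) {
    stop("census species without a PFT assignment: ",
         paste(unique(census$species[is.na(pft)]), collapse = ", "),
         call. = FALSE)
  }
  d <- census$dbh_cm / 100
  height <- if ("height_m" %in% names(census)) census$height_m else NULL
  agb_i <- tree_agb(d, pft, params, height = height)
  ba_i <- (pi / 4) * d^2

  by_pft <- tibble::tibble(pft = pft, agb = agb_i, basal_area = ba_i) |>
    dplyr::group_by(.data$pft) |>
    dplyr::summarise(agb = sum(.data$agb) * up,
                     basal_area = sum(.data$basal_area) * up,
                     stems = dplyr::n() * up, .groups = "drop")
  by_pft <- dplyr::left_join(tibble::tibble(pft = pfts), by_pft, by = "pft") |>
    dplyr::mutate(dplyr::across(c("agb", "basal_area", "stems"),
                                ~ tidyr::replace_na(.x, 0)))
  total <- dplyr::summarise(by_pft, agb = sum(.data$agb),
                            basal_area = sum(.data$basal_area),
                            stems = sum(.data$stems))
  sd_tbl <- size_distribution_bins(census$dbh_cm, bin_width_cm, scale = up)
  structure(list(by_pft = by_pft, total = total, size_distribution = sd_tbl,
                 upscaling_factor = up),
            class = "field_targets")
}

size_distribution_bins <- function(dbh_cm, bin_width_cm = 10, scale = 1,
                                   min_cm = 10, max_cm = 160) {
  breaks <- seq(min_cm, max_cm, by = bin_width_cm)
  lab <- paste0(utils::head(breaks, -1), "-", breaks[-1])
  counts <- if (length(dbh_cm) == 0) {
    rep(0, length(lab))
  } else {
    as.numeric(table(cut(pmin(dbh_cm, max_cm - 1e-9), breaks = breaks,
                         labels = lab, right = FALSE)))
  }
  tibble::tibble(dbh_class = lab,
                 dbh_lower_cm = utils::head(breaks, -1),
                 stems = counts * scale)
}

#' @export
print.field_targets <- function(x, ...) {
  cat("Field inventory targets (per hectare; upscaling factor ",
      x$upscaling_factor, ")\n", sep = "")
  cat("Total: AGB ", round(x$total$agb, 1), " t_odm/ha, basal area ",
      round(x$total$basal_area, 1), " m2/ha, ",
      round(x$total$stems, 0), " stems/ha\n", sep = "")
  print(x$by_pft, ...)
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @export
tidy.field_targets <- function(x, ...) {
  dplyr::bind_rows(
    dplyr::mutate(x$by_pft, pft = as.character(.data$pft)),
    dplyr::mutate(x$total, pft = "total")
  ) |>
    dplyr::relocate("pft")
}
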