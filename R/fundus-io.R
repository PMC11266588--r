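#' Diagnosis code vocabulary
#'
#' Maps the integer diagnosis codes used in the infant retinal image naming
#' convention to their clinical labels.  Codes 0--13 cover the physiological
#' finding, retinopathy of prematurity (ROP) stages 0--5 (4A/4B split),
#' aggressive ROP, status post ROP, and the non-ROP diagnoses recorded in
#' the cohort.
#'
#' @param code Integer vector of diagnosis codes in 0..13.
#' @return Character vector of labels.
#' @examples
#' diagnosis_label(c(0, 2, 11))
#' @export
diagnosis_label <- function(code) {
  labels <- c(
    "Physiological", "ROP 0", "ROP 1", "ROP 2", "ROP 3", "ROP 4A",
    "ROP 4B", "ROP 5", "A-ROP", "St.p. ROP", "Hamartomas", "Haemorrhage",
    "Hypoplasia n.II", "Toxoplasma"
  )
  if (length(code) == 0) return(character())
  if (anyNA(code) || !all(code == trunc(code)) || any(code < 0 | code > 13)) {
    bad <- code[is.na(code) | code != trunc(code) | code < 0 | code > 13]
    abort(sprintf("diagnosis code out of range 0..13: %s",
                  paste(utils::head(bad, 3), collapse = ", ")))
  }
  labels[code + 1L]
}

plus_form_label <- function(pf) c("normal", "pre-plus", "plus")[pf + 1L]

.device_tokens <- c(RC3 = 1L, RE = 2L, ICON = 3L)

metadata_cols <- c(
  "patient_id", "sex", "gestational_age_weeks", "birth_weight_g",
  "postconceptual_age_weeks", "diagnosis_code", "plus_form", "device",
  "device_token", "series", "image_index"
)

validate_metadata <- function(meta) {
  chk <- function(ok, what) {
    if (!all(ok)) {
      abort(sprintf("invalid metadata: %s (row %d)", what, which(!ok)[1]))
    }
  }
  chk(!is.na(meta$patient_id) & meta$patient_id >= 1, "patient_id must be a positive integer")
  chk(meta$sex %in% c("F", "M"), "sex must be 'F' or 'M'")
  chk(!is.na(meta$gestational_age_weeks) &
        meta$gestational_age_weeks >= 20 & meta$gestational_age_weeks <= 45,
      "gestational_age_weeks outside [20, 45]")
  chk(!is.na(meta$birth_weight_g) &
        meta$birth_weight_g >= 300 & meta$birth_weight_g <= 5000,
      "birth_weight_g outside [300, 5000]")
  chk(!is.na(meta$postconceptual_age_weeks) &
        meta$postconceptual_age_weeks >= meta$gestational_age_weeks,
      "postconceptual_age_weeks below gestational_age_weeks")
  chk(meta$diagnosis_code %in% 0:13, "diagnosis_code outside 0..13")
  chk(meta$plus_form %in% 0:2, "plus_form outside {0, 1, 2}")
  chk(meta$device %in% 1:3, "device outside {1, 2, 3}")
  chk(!is.na(meta$series) & meta$series >= 1, "series must be a positive integer")
  chk(!is.na(meta$image_index) & meta$image_index >= 1, "image_index must be a positive integer")
  invisible(meta)
}

#' Parse convention-compliant fundus image filenames
#'
#' Decodes base filenames of the form
#' `ID_sex_GAxx_BWxxxx_PAxx_DGx_PFx_device_Sxx_n.jpg` into a tibble of image
#' metadata, one row per name.  The device token is normalized to an integer
#' (`RC3` -> 1, `RE` -> 2, `ICON` -> 3; bare digits 1/2/3 pass through); the
#' verbatim token is kept in `device_token`.
#'
#' @param name Character vector of base filenames, with or without a
#'   `.jpg`/`.jpeg`/`.png` extension and leading directories.
#' @return A tibble with columns `patient_id`, `sex`,
#'   `gestational_age_weeks`, `birth_weight_g`, `postconceptual_age_weeks`,
#'   `diagnosis_code`, `plus_form`, `device`, `device_token`, `series`,
#'   `image_index`, `name`.
#' @examples
#' parse_fundus_filename("001_F_GA41_BW2905_PA44_DG2_PF0_RC3_S01_1.jpg")
#' @export
parse_fundus_filename <- function(name) {
  base <- sub("\\.(jpg|jpeg|png)$", "", basename(name), ignore.case = TRUE)
  rows <- lapply(seq_along(base), function(i) parse_one_filename(base[i], name[i]))
  out <- dplyr::bind_rows(rows)
  validate_metadata(out)
  out
}

parse_one_filename <- function(base, original) {
  tok <- strsplit(base, "_", fixed = TRUE)[[1]]
  if (length(tok) != 10L) {
    abort(sprintf("cannot parse '%s': expected 10 underscore-separated fields, got %d",
                  original, length(tok)))
  }
  num <- function(field, prefix) {
    if (!startsWith(field, prefix)) {
      abort(sprintf("cannot parse '%s': field '%s' does not start with '%s'",
                    original, field, prefix))
    }
    v <- substring(field, nchar(prefix) + 1L)
    if (!grepl("^[0-9]+$", v)) {
      abort(sprintf("cannot parse '%s': field '%s' is not numeric", original, field))
    }
    as.integer(v)
  }
  if (!grepl("^[0-9]+$", tok[1])) {
    abort(sprintf("cannot parse '%s': patient id '%s' is not numeric", original, tok[1]))
  }
  if (!tok[2] %in% c("F", "M")) {
    abort(sprintf("cannot parse '%s': sex token '%s' is not F/M", original, tok[2]))
  }
  device_token <- tok[8]
  device <- if (device_token %in% names(.device_tokens)) {
    .device_tokens[[device_token]]
  } else if (grepl("^[123]$", device_token)) {
    as.integer(device_token)
  } else {
    abort(sprintf("cannot parse '%s': unknown device token '%s'", original, device_token))
  }
  if (!grepl("^[0-9]+$", tok[10])) {
    abort(sprintf("cannot parse '%s': image number '%s' is not numeric", original, tok[10]))
  }
  tibble(
    patient_id = as.integer(tok[1]),
    sex = tok[2],
    gestational_age_weeks = num(tok[3], "GA"),
    birth_weight_g = num(tok[4], "BW"),
    postconceptual_age_weeks = num(tok[5], "PA"),
    diagnosis_code = num(tok[6], "DG"),
    plus_form = num(tok[7], "PF"),
    device = device,
    device_token = device_token,
    series = num(tok[9], "S"),
    image_index = as.integer(tok[10]),
    name = original
  )
}

#' Format image metadata back into convention filenames
#'
#' Inverse of [parse_fundus_filename()]: emits the canonical token order
#' `ID_sex_GAx_BWx_PAx_DGx_PFx_device_Sxx_n` with the patient id zero-padded
#' to width 3 and the series to width 2.
#'
#' @param meta Tibble/data frame with the metadata columns produced by
#'   [parse_fundus_filename()] (`device_token` optional; falls back to the
#'   numeric `device`).
#' @param ext Extension to append, `""` for none.
#' @return Character vector of filenames.
#' @export
format_fundus_filename <- function(meta, ext = "") {
  meta <- as_tibble(meta)
  if (!"device_token" %in% names(meta)) {
    meta$device_token <- as.character(meta$device)
  }
  validate_metadata(meta)
  sprintf(
    "%03d_%s_GA%d_BW%d_PA%d_DG%d_PF%d_%s_S%02d_%d%s",
    meta$patient_id, meta$sex, meta$gestational_age_weeks, meta$birth_weight_g,
    meta$postconceptual_age_weeks, meta$diagnosis_code, meta$plus_form,
    meta$device_token, meta$series, meta$image_index, ext
  )
}

#' Catalog a dataset tree or metadata workbook
#'
#' Builds a catalog (one row per image) either from a folder tree of
#' convention-named images (the `images/`, `images_stack/` and
#' `images_stack_without_captions/` mirror layouts are deduplicated by
#' basename) or from a metadata table (`.xlsx` workbook via readxl, or
#' `.csv`/`.tsv`) using the naming convention's column vocabulary.
#'
#' Files that do not parse are collected into the `skipped` attribute rather
#' than failing the scan.
#'
#' @param root Path to a dataset folder or to a metadata workbook/table.
#' @return A `fundus_catalog` tibble of image metadata with attributes
#'   `source` (`"folder_tree"` or `"workbook"`) and `skipped` (character
#'   vector of unparseable files).
#' @export
scan_fundus_dataset <- function(root) {
  if (dir.exists(root)) {
    files <- list.files(root, recursive = TRUE, full.names = TRUE)
    files <- files[!dir.exists(files)]
    img <- files[grepl("\\.(jpg|jpeg|png)$", files, ignore.case = TRUE)]
    other <- files[!grepl("\\.(jpg|jpeg|png)$", files, ignore.case = TRUE)]
    # mask files written alongside synthetic images are not catalog entries
    other <- c(other, img[grepl("_mask[0-9]*\\.png$", img)])
    img <- img[!grepl("_mask[0-9]*\\.png$", img)]
    keep <- !duplicated(basename(img))
    img <- img[keep]
    skipped <- basename(other)
    rows <- vector("list", length(img))
    for (i in seq_along(img)) {
      rows[[i]] <- tryCatch(parse_fundus_filename(img[i]),
                            error = function(e) NULL)
      if (is.null(rows[[i]])) skipped <- c(skipped, basename(img[i]))
    }
    out <- dplyr::bind_rows(rows)
    if (nrow(out)) {
      out$path <- img[!vapply(rows, is.null, logical(1))]
      out$name <- basename(out$name)
    }
    if (nrow(out) == 0) warn(sprintf("empty catalog: no parseable images under %s", root))
    src <- "folder_tree"
  } else if (file.exists(root)) {
    out <- read_metadata_table(root)
    skipped <- character()
    src <- "workbook"
  } else {
    abort(sprintf("dataset root not found: %s", root))
  }
  if (nrow(out) && anyDuplicated(out[c("patient_id", "series", "image_index")])) {
    abort("catalog invariant violated: duplicated (patient, series, image) triple")
  }
  new_fundus_catalog(out, source = src, skipped = unique(skipped))
}

new_fundus_catalog <- function(tbl, source, skipped = character()) {
  out <- as_tibble(tbl)
  attr(out, "source") <- source
  attr(out, "skipped") <- skipped
  class(out) <- c("fundus_catalog", class(out))
  out
}

# Accepts the workbook column vocabulary (ID, SEX, GESTATIONAL_AGE,
# BIRTH_WEIGHT, POSTCONCEPTUAL_AGE, DIAGNOSIS_CODE, PLUS_FORM, DEVICE,
# SERIES_NUMBER [, IMAGE_NUMBER]) case-insensitively, or this package's own
# column names.
read_metadata_table <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE)) {
        abort("reading .xlsx requires the readxl package")
      }
      readxl::read_excel(path)
    },
    csv = readr::read_csv(path, show_col_types = FALSE),
    tsv = readr::read_tsv(path, show_col_types = FALSE),
    abort(sprintf("unsupported metadata format '.%s'", ext))
  )
  names(raw) <- toupper(names(raw))
  alias <- c(
    ID = "patient_id", PATIENT_ID = "patient_id", SEX = "sex",
    GESTATIONAL_AGE = "gestational_age_weeks",
    GESTATIONAL_AGE_WEEKS = "gestational_age_weeks",
    BIRTH_WEIGHT = "birth_weight_g", BIRTH_WEIGHT_G = "birth_weight_g",
    POSTCONCEPTUAL_AGE = "postconceptual_age_weeks",
    POSTCONCEPTUAL_AGE_WEEKS = "postconceptual_age_weeks",
    DIAGNOSIS_CODE = "diagnosis_code", PLUS_FORM = "plus_form",
    DEVICE = "device", DEVICE_TOKEN = "device_token",
    SERIES_NUMBER = "series", SERIES = "series",
    IMAGE_NUMBER = "image_index", IMAGE_INDEX = "image_index",
    NAME = "name", PATH = "path"
  )
  hit <- names(raw) %in% names(alias)
  out <- raw[hit]
  names(out) <- alias[names(out)]
  missing <- setdiff(setdiff(metadata_cols, c("device_token", "image_index")), names(out))
  if (length(missing)) {
    abort(sprintf("metadata table %s lacks columns: %s", path,
                  paste(missing, collapse = ", ")))
  }
  if (!"image_index" %in% names(out)) {
    out <- dplyr::mutate(
      dplyr::group_by(out, .data$patient_id, .data$series),
      image_index = dplyr::row_number()
    )
    out <- dplyr::ungroup(out)
  }
  if (!"device_token" %in% names(out)) out$device_token <- as.character(out$device)
  int_cols <- setdiff(metadata_cols, c("sex", "device_token"))
  out[int_cols] <- lapply(out[int_cols], as.integer)
  validate_metadata(out)
  as_tibble(out)
}

#' Cohort summary statistics for an image catalog
#'
#' Summarizes a catalog the way the dataset overview tables do: gestational
#' age and birth weight are patient-level statistics (over unique patients),
#' postconceptual age is a series-level statistic (over unique
#' patient/series pairs), and counts of patients, images and series are
#' reported in total and by sex, device, plus form and diagnosis code.
#' Standard deviations use the population (denominator n) definition, and
#' the published overview prints integer-rounded means, so half-up rounded
#' values are reported alongside the raw ones.
#'
#' @param catalog A `fundus_catalog` tibble (or any tibble with the metadata
#'   columns).
#' @return A `fundus_summary` list with tibbles `numeric` (variable, level,
#'   mean, min, max, std, mean_rounded, std_rounded, n) and `counts` (unit,
#'   variable, level, n).
#' @export
summarize_cohort <- function(catalog) {
  catalog <- as_tibble(catalog)
  if (nrow(catalog) == 0) abort("cannot summarize an empty catalog")

  pop_sd <- function(x) sqrt(mean((x - mean(x))^2))
  round_half_up <- function(x) floor(x + 0.5)

  patients <- dplyr::distinct(catalog, .data$patient_id, .keep_all = TRUE)
  series <- dplyr::distinct(catalog, .data$patient_id, .data$series, .keep_all = TRUE)

  stat_row <- function(x, variable, level) {
    tibble(
      variable = variable, level = level,
      mean = mean(x), min = min(x), max = max(x), std = pop_sd(x),
      mean_rounded = round_half_up(mean(x)), std_rounded = round_half_up(pop_sd(x)),
      n = length(x)
    )
  }
  numeric_tbl <- dplyr::bind_rows(
    stat_row(patients$gestational_age_weeks, "gestational_age", "patient"),
    stat_row(patients$birth_weight_g, "birth_weight", "patient"),
    stat_row(series$postconceptual_age_weeks, "postconceptual_age", "series")
  )

  count_by <- function(tbl, unit, var) {
    if (is.null(var)) {
      tibble(unit = unit, variable = "total", level = "all", n = nrow(tbl))
    } else {
      out <- dplyr::count(tbl, level = as.character(.data[[var]]))
      tibble(unit = unit, variable = var, level = out$level, n = out$n)
    }
  }
  units <- list(patient = patients, image = catalog, series = series)
  counts <- dplyr::bind_rows(lapply(names(units), function(u) {
    dplyr::bind_rows(
      count_by(units[[u]], u, NULL),
      count_by(units[[u]], u, "sex"),
      count_by(units[[u]], u, "device"),
      count_by(units[[u]], u, "plus_form"),
      count_by(units[[u]], u, "diagnosis_code")
    )
  }))

  structure(list(numeric = numeric_tbl, counts = counts),
            class = "fundus_summary")
}

#' @export
print.fundus_summary <- function(x, ...) {
  cat("Cohort summary\n\nNumeric variables:\n")
  print(x$numeric, ...)
  cat("\nCounts (head):\n")
  print(utils::head(x$counts, 12), ...)
  invisible(x)
}

#' @export
print.fundus_catalog <- function(x, ...) {
  skipped <- attr(x, "skipped")
  cat(sprintf("Fundus image catalog: %d records (source: %s, %d skipped)\n",
              nrow(x), attr(x, "source") %||% "?", length(skipped)))
  NextMethod()
}
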