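# Harmonisation of heterogeneous per-study metadata onto fixed categories.

.location_lookup <- list(
  NorthAmerica = c("north america", "northamerica", "usa", "us", "united states",
                   "united states of america", "canada"),
  Europe = c("europe", "uk", "united kingdom", "england", "germany", "france",
             "spain", "italy", "netherlands", "sweden", "denmark", "norway",
             "finland", "ireland", "portugal", "austria", "belgium", "poland",
             "switzerland", "greece"),
  China = c("china", "prc")
)

.level_sets <- list(
  location    = c("NorthAmerica", "Europe", "China", "others"),
  region      = c("V3V4", "V4", "others"),
  sample_type = c("spit", "mouthwash", "oral_rinse", "others"),
  gender      = c("male", "female", "unknown"),
  age_group   = c("18-30", "31-55", "56+", "unknown"),
  smoking     = c("smoker", "non_smoker", "unknown"),
  drinking    = c("drinker", "non_drinker", "unknown")
)

#' Harmonise raw per-sample metadata
#'
#' Maps heterogeneous per-study fields onto the harmonised categories used
#' throughout the package:
#'
#' * ages are binned into `18-30`, `31-55` and `56+`;
#' * any use of e-cigarettes or tobacco makes a sample `smoker`;
#' * any alcohol use, regardless of frequency or type, makes it `drinker`;
#' * geographic locations outside North America, Europe and China become
#'   `others`, as do hypervariable regions other than V3-V4/V4 and collection
#'   methods other than spit, mouthwash and oral rinse (swabs in particular);
#' * missing host fields become `unknown`.
#'
#' Recognised input columns (all optional except `sample_id` and `study`):
#' `location`/`country`, `region`, `sample_type`, `gender`/`sex`, `age` (numeric)
#' or `age_group`, `smoking` plus the finer `smokes_ecig`/`smokes_tobacco`,
#' `drinking`/`alcohol`.
#'
#' @param raw Data frame of per-sample key-value fields.
#' @return Data frame with columns `sample_id`, `study`, `location`, `region`,
#'   `sample_type`, `gender`, `age_group`, `smoking`, `drinking`.
#' @export
harmonise_metadata <- function(raw) {
  if (!is.data.frame(raw)) stop("raw metadata must be a data frame", call. = FALSE)
  if (is.null(raw$sample_id) || is.null(raw$study)) {
    stop("raw metadata must contain 'sample_id' and 'study' columns", call. = FALSE)
  }
  n <- nrow(raw)
  get_chr <- function(...) {
    for (nm in c(...)) if (!is.null(raw[[nm]])) return(trimws(as.character(raw[[nm]])))
    rep(NA_character_, n)
  }

  loc_raw <- tolower(get_chr("location", "country"))
  location <- rep("others", n)
  for (lv in names(.location_lookup)) {
    location[loc_raw %in% .location_lookup[[lv]]] <- lv
  }
  location[loc_raw %in% c("europe")] <- "Europe"

  reg_raw <- toupper(gsub("[ _-]", "", get_chr("region", "hypervariable_region")))
  region <- rep("others", n)
  region[reg_raw %in% "V3V4"] <- "V3V4"
  region[reg_raw %in% "V4"] <- "V4"

  st_raw <- tolower(gsub("[ -]", "_", get_chr("sample_type", "collection")))
  sample_type <- rep("others", n)
  sample_type[st_raw %in% "spit"] <- "spit"
  sample_type[st_raw %in% "mouthwash"] <- "mouthwash"
  sample_type[st_raw %in% c("oral_rinse", "rinse")] <- "oral_rinse"

  g_raw <- tolower(get_chr("gender", "sex"))
  gender <- rep("unknown", n)
  gender[g_raw %in% c("male", "m")] <- "male"
  gender[g_raw %in% c("female", "f")] <- "female"

  age_group <- rep("unknown", n)
  if (!is.null(raw$age_group)) {
    ag <- as.character(raw$age_group)
    age_group[ag %in% .level_sets$age_group] <- ag[ag %in% .level_sets$age_group]
  } else if (!is.null(raw$age)) {
    age <- suppressWarnings(as.numeric(raw$age))
    age_group[!is.na(age) & age >= 18 & age <= 30] <- "18-30"
    age_group[!is.na(age) & age >= 31 & age <= 55] <- "31-55"
    age_group[!is.na(age) & age >= 56] <- "56+"
  }

  truthy <- function(x) {
    x <- tolower(as.character(x))
    out <- rep(NA, n)
    out[x %in% c("true", "t", "yes", "y", "1", "smoker", "drinker", "current")] <- TRUE
    out[x %in% c("false", "f", "no", "n", "0", "non_smoker", "nonsmoker",
                 "non-smoker", "non_drinker", "nondrinker", "non-drinker", "never")] <- FALSE
    out
  }
  smoke_any <- truthy(get_chr("smoking", "smoker"))
  for (col in c("smokes_ecig", "smokes_tobacco")) {
    if (!is.null(raw[[col]])) {
      v <- truthy(raw[[col]])
      smoke_any <- ifelse(is.na(smoke_any), v, smoke_any | (!is.na(v) & v))
    }
  }
  smoking <- ifelse(is.na(smoke_any), "unknown", ifelse(smoke_any, "smoker", "non_smoker"))

  drink_any <- truthy(get_chr("drinking", "drinker", "alcohol"))
  drinking <- ifelse(is.na(drink_any), "unknown", ifelse(drink_any, "drinker", "non_drinker"))

  out <- data.frame(
    sample_id = as.character(raw$sample_id),
    study = as.character(raw$study),
    location = location, region = region, sample_type = sample_type,
    gender = gender, age_group = age_group, smoking = smoking,
    drinking = drinking, stringsAsFactors = FALSE
  )
  if (anyDuplicated(out$sample_id)) stop("duplicated sample ids in metadata", call. = FALSE)
  out
}

#' Drop samples with uninformative levels of one category
#'
#' Samples whose value for `category` is `unknown` (and optionally `others`)
#' are excluded from analyses of that category only; other analyses keep them.
#'
#' @param meta Harmonised metadata.
#' @param category Column name.
#' @param drop Levels treated as uninformative.
#' @return Metadata restricted to informative samples for `category`.
#' @export
drop_unknown <- function(meta, category, drop = "unknown") {
  if (is.null(meta[[category]])) stop("no such category: ", category, call. = FALSE)
  meta[!(meta[[category]] %in% drop), , drop = FALSE]
}

category_levels <- function(category) .level_sets[[category]]
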