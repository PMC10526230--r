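#' @title Ordinal semantic attributes and their binary re-categorization
#' @name semantics
#' @description
#' Lung-nodule CADx datasets annotate each nodule with ordinal semantic
#' attributes: malignancy suspicion, margin sharpness, sphericity, subtlety
#' (conspicuity against the surroundings) and internal texture on 1--5
#' scales, and calcification on a 1--6 scale whose sixth level means
#' "absent". For binary classification these are re-categorized to two
#' levels: the 5-level attributes map levels 1--3 to 0 (negative) and 4--5
#' to 1 (positive); calcification maps levels 1--5 (calcification present)
#' to 0 and level 6 (absent) to 1.
NULL

# canonical attribute order used throughout the package: the five semantic
# branch tasks (alphabetical) followed by the fused malignancy task
SEMANTIC_FEATURES <- c("calcification", "margin", "sphericity", "subtlety", "texture")
ALL_FEATURES <- c(SEMANTIC_FEATURES, "malignancy")

#' Number of ordinal levels per attribute
#'
#' Calcification is the only 6-level attribute; all others have 5 levels.
#'
#' @return Named integer vector of level counts for the six attributes.
#' @export
attribute_levels <- function() {
  out <- c(calcification = 6L, margin = 5L, sphericity = 5L,
           subtlety = 5L, texture = 5L, malignancy = 5L)
  out[ALL_FEATURES]
}

# text labels accepted by parse_ordinal(), per-feature, index = level
.level_labels <- list(
  malignancy = c("Highly unlikely", "Moderately unlikely", "Indeterminate",
                 "Moderately suspicious", "Highly suspicious"),
  margin = c("Poorly defined", NA, NA, NA, "Sharp"),
  sphericity = c("Linear", NA, "Ovoid", NA, "Round"),
  subtlety = c("Extremely subtle", "Moderately subtle", "Fairly subtle",
               "Moderately obvious", "Obvious"),
  texture = c("Non-solid", NA, "Part Solid", NA, "Solid"),
  calcification = c("Popcorn", "Laminated", "Solid", "Non-central",
                    "Central", "Absent")
)

#' Validate a set of ordinal attribute levels
#'
#' @param attrs Named list, named vector, or one-row data.frame with integer
#'   components `malignancy`, `margin`, `sphericity`, `subtlety`, `texture`
#'   (levels 1--5) and `calcification` (levels 1--6).
#' @return The attributes as a named integer vector in canonical order,
#'   invisibly usable downstream. Errors name the offending feature.
#' @export
validate_ordinal <- function(attrs) {
  attrs <- as.list(attrs)
  missing <- setdiff(ALL_FEATURES, names(attrs))
  if (length(missing)) {
    stop("missing ordinal attribute(s): ", paste(missing, collapse = ", "))
  }
  lev <- attribute_levels()
  out <- integer(length(ALL_FEATURES))
  names(out) <- ALL_FEATURES
  for (f in ALL_FEATURES) {
    v <- attrs[[f]]
    if (length(v) != 1L || !is.finite(v) || v != as.integer(v)) {
      stop("attribute '", f, "' must be a single integer level")
    }
    v <- as.integer(v)
    if (v < 1L || v > lev[[f]]) {
      stop("attribute '", f, "' level ", v, " outside valid range 1-", lev[[f]])
    }
    out[[f]] <- v
  }
  out
}

#' Binarize ordinal semantic attributes
#'
#' Applies the two-level re-categorization: malignancy, margin, sphericity,
#' subtlety and texture levels 1--3 map to 0 and levels 4--5 to 1;
#' calcification levels 1--5 (calcification present) map to 0 and level 6
#' (absent) to 1.
#'
#' @param attrs A single attribute set (named list/vector accepted by
#'   [validate_ordinal()]) or a data.frame with one row per nodule and the
#'   six ordinal columns.
#' @return For a single attribute set, a named integer 0/1 vector over the
#'   six features; for a data.frame, the input with added `<feature>_bin`
#'   columns.
#' @examples
#' binarize(list(malignancy = 3, margin = 4, sphericity = 1, subtlety = 5,
#'               texture = 2, calcification = 6))
#' @export
binarize <- function(attrs) {
  if (is.data.frame(attrs)) {
    for (f in ALL_FEATURES) {
      if (!f %in% names(attrs)) stop("missing ordinal column '", f, "'")
    }
    n <- nrow(attrs)
    for (i in seq_len(n)) validate_ordinal(attrs[i, ALL_FEATURES, drop = FALSE])
    for (f in ALL_FEATURES) {
      attrs[[paste0(f, "_bin")]] <- .binarize_one(f, as.integer(attrs[[f]]))
    }
    return(attrs)
  }
  a <- validate_ordinal(attrs)
  out <- vapply(ALL_FEATURES, function(f) .binarize_one(f, a[[f]]), integer(1))
  names(out) <- ALL_FEATURES
  out
}

.binarize_one <- function(feature, level) {
  if (feature == "calcification") {
    as.integer(level == 6L)   # 1 = absence of calcification
  } else {
    as.integer(level >= 4L)
  }
}

#' Parse ordinal levels given numerically or as text labels
#'
#' Upstream label tables may carry either numeric levels or the standard
#' text labels ("Absent", "Obvious", "Part Solid", ...). Matching is
#' case-insensitive; numeric strings are accepted.
#'
#' @param feature Attribute name.
#' @param x Vector of levels (numeric, or character labels).
#' @return Integer vector of ordinal levels.
#' @export
parse_ordinal <- function(feature, x) {
  feature <- match.arg(feature, ALL_FEATURES)
  if (is.numeric(x)) return(vapply(x, function(v) {
    validate_ordinal(.with_level(feature, v))[[feature]]
  }, integer(1)))
  x <- as.character(x)
  suppressWarnings(num <- as.numeric(x))
  labs <- tolower(.level_labels[[feature]])
  out <- integer(length(x))
  for (i in seq_along(x)) {
    if (!is.na(num[i])) {
      out[i] <- validate_ordinal(.with_level(feature, num[i]))[[feature]]
    } else {
      m <- match(tolower(trimws(x[i])), labs)
      if (is.na(m)) {
        stop("attribute '", feature, "': unrecognized level label '", x[i], "'")
      }
      out[i] <- m
    }
  }
  out
}

# helper: a full valid attribute set with one feature set to `v`
.with_level <- function(feature, v) {
  a <- as.list(c(malignancy = 1, margin = 1, sphericity = 1, subtlety = 1,
                 texture = 1, calcification = 1))
  a[[feature]] <- v
  a
}

#' Read a nodule label table from CSV
#'
#' Expects columns `id` plus the six ordinal attribute columns; levels may
#' be numeric or text labels. Binary columns suffixed `_bin` are derived.
#'
#' @param path CSV file path.
#' @return data.frame with `id`, ordinal columns (integer) and `_bin` columns.
#' @export
read_label_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"id" %in% names(df)) stop("label table must have an 'id' column")
  for (f in ALL_FEATURES) {
    if (!f %in% names(df)) stop("missing ordinal column '", f, "'")
    df[[f]] <- parse_ordinal(f, df[[f]])
  }
  binarize(df)
}

#' Write a nodule label table (ordinal + derived binary columns) to CSV
#'
#' @param df data.frame with `id` and the six ordinal columns.
#' @param path Output CSV path.
#' @return Invisibly, the written data.frame (with `_bin` columns).
#' @export
write_label_table <- function(df, path) {
  df <- binarize(df)
  cols <- c("id", ALL_FEATURES, paste0(ALL_FEATURES, "_bin"))
  utils::write.csv(df[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(df)
}
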