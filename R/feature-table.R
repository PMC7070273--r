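#' Feature table: samples x named features with age labels
#'
#' The common container passed between all pipeline stages: a numeric matrix
#' of area features (rows = samples, columns = named features) together with
#' sample identifiers and, optionally, the marked age of each wine sample in
#' years. E-tongue tables carry 18 columns (`E{1..3}{a,b}{1..3}` = electrode
#' x waveform x frequency phase), e-nose tables 24 (`S{1..12}a{1,2}` =
#' sensor x taste/aftertaste window), fused tables 42.
#'
#' @param features numeric matrix with unique column names; no missing values.
#' @param sample_id character vector of row identifiers (defaults to
#'   `rownames(features)`).
#' @param age_years optional numeric vector of marked ages (one per row).
#' @return An object of class `feature_table` with elements `features`,
#'   `sample_id`, `age_years`.
#' @examples
#' m <- matrix(rnorm(12), 4, 3, dimnames = list(paste0("s", 1:4), c("a", "b", "c")))
#' ft <- feature_table(m, age_years = c(3, 5, 8, 10))
#' dim(ft)
#' @export
feature_table <- function(features, sample_id = rownames(features),
                          age_years = NULL) {
  features <- as.matrix(features)
  if (is.null(colnames(features)) || anyDuplicated(colnames(features))) {
    stopf("feature names must be present and unique")
  }
  if (anyNA(features)) stopf("feature table contains missing values")
  if (is.null(sample_id)) sample_id <- sprintf("s%03d", seq_len(nrow(features)))
  sample_id <- as.character(sample_id)
  if (length(sample_id) != nrow(features)) {
    stopf("sample_id length (%d) != number of rows (%d)",
          length(sample_id), nrow(features))
  }
  if (anyDuplicated(sample_id)) stopf("sample_id values must be unique")
  rownames(features) <- sample_id
  if (!is.null(age_years)) {
    age_years <- as.numeric(age_years)
    if (length(age_years) != nrow(features)) {
      stopf("age_years length (%d) != number of rows (%d)",
            length(age_years), nrow(features))
    }
  }
  structure(
    list(features = features, sample_id = sample_id, age_years = age_years),
    class = "feature_table"
  )
}

#' @export
dim.feature_table <- function(x) dim(x$features)

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %d samples x %d features\n",
              nrow(x$features), ncol(x$features)))
  cat("  features:", paste(utils::head(colnames(x$features), 6), collapse = ", "),
      if (ncol(x$features) > 6) "..." else "", "\n")
  if (!is.null(x$age_years)) {
    cat("  ages:", paste(sort(unique(x$age_years)), collapse = ", "), "years\n")
  }
  invisible(x)
}

#' @export
as.data.frame.feature_table <- function(x, ...) {
  df <- data.frame(sample_id = x$sample_id, x$features,
                   check.names = FALSE, row.names = NULL)
  if (!is.null(x$age_years)) df$age_years <- x$age_years
  df
}

# Row subset preserving labels.
ft_subset <- function(ft, idx) {
  feature_table(ft$features[idx, , drop = FALSE],
                sample_id = ft$sample_id[idx],
                age_years = if (!is.null(ft$age_years)) ft$age_years[idx])
}

# Column subset preserving labels.
ft_select <- function(ft, cols) {
  feature_table(ft$features[, cols, drop = FALSE],
                sample_id = ft$sample_id,
                age_years = ft$age_years)
}
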