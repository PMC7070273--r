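# Plain-text interchange: long-format trace CSVs and feature CSVs.

#' Write / read traces as long-format CSV
#'
#' Columns: `sample_id`, `device`, `channel_id`, `time_s`, `value`.
#'
#' @param traces list of [signal_trace()] objects.
#' @param path CSV file path.
#' @return `write_traces_csv()` returns `path` invisibly;
#'   `read_traces_csv()` returns a list of [signal_trace()]s.
#' @export
write_traces_csv <- function(traces, path) {
  dfs <- lapply(traces, function(tr) {
    data.frame(sample_id = tr$sample_id, device = tr$device,
               channel_id = tr$channel_id, time_s = tr$time_s,
               value = tr$value)
  })
  utils::write.csv(do.call(rbind, dfs), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_traces_csv
#' @export
read_traces_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  key <- paste(df$sample_id, df$device, df$channel_id, sep = "\r")
  lapply(split(df, factor(key, levels = unique(key))), function(d) {
    signal_trace(d$sample_id[1], d$device[1], d$channel_id[1],
                 d$time_s, d$value)
  }) |> unname()
}

#' Write / read a feature table as CSV
#'
#' One row per sample: `sample_id`, the named features, and `age_years`
#' when labels are present.
#'
#' @param table a [feature_table()].
#' @param path CSV file path.
#' @return `write_features_csv()` returns `path` invisibly;
#'   `read_features_csv()` returns a [feature_table()].
#' @export
write_features_csv <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_features_csv
#' @export
read_features_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  age <- if ("age_years" %in% names(df)) df$age_years
  keep <- setdiff(names(df), c("sample_id", "age_years"))
  feature_table(as.matrix(df[keep]), sample_id = df$sample_id,
                age_years = age)
}
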