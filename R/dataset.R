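#' Construct a twin-pair dataset
#'
#' Wide format: one row per family with the zygosity group, each twin's sex
#' and the shared age, and per-twin trait columns `<trait>_1`, `<trait>_2`.
#' A missing co-twin is an all-`NA` set of trait columns for that twin.
#'
#' @param data Data frame with columns `family_id`, `zygosity` (one of
#'   `"MZm"`, `"DZm"`, `"MZf"`, `"DZf"`, `"DOS"`), `age`, `sex1`, `sex2`
#'   (0 = female, 1 = male) and `<trait>_1`/`<trait>_2` for every trait in
#'   `specs`.
#' @param specs Measurement specification as from [psqi_specs()]: columns
#'   `trait`, `measure`, `n_cat`.
#' @return An object of class `twin_dataset`.
#' @export
twin_dataset <- function(data, specs = psqi_specs()) {
  req <- c("family_id", "zygosity", "age", "sex1", "sex2",
           paste0(rep(specs$trait, each = 2L), c("_1", "_2")))
  miss <- setdiff(req, names(data))
  if (length(miss))
    stop_input("missing columns: %s", paste(miss, collapse = ", "))
  bad <- setdiff(unique(as.character(data$zygosity)), zygosity_groups())
  if (length(bad))
    stop_input("unknown zygosity labels: %s", paste(bad, collapse = ", "))
  for (k in which(specs$measure == "ordinal")) {
    tr <- specs$trait[k]
    v <- c(data[[paste0(tr, "_1")]], data[[paste0(tr, "_2")]])
    v <- v[!is.na(v)]
    if (length(v) && (any(v != round(v)) || any(v < 0) ||
                      any(v > specs$n_cat[k] - 1L)))
      stop_input("ordinal trait '%s' outside 0..%d", tr, specs$n_cat[k] - 1L)
  }
  structure(list(data = as.data.frame(data), specs = specs),
            class = "twin_dataset")
}

#' The five zygosity group labels of the cohort design
#'
#' @return `c("MZm", "DZm", "MZf", "DZf", "DOS")`: monozygotic male/female,
#'   dizygotic same-sex male/female, and dizygotic opposite-sex pairs.
#' @export
zygosity_groups <- function() c("MZm", "DZm", "MZf", "DZf", "DOS")

# MZ vs DZ relatedness class for each record
relatedness_class <- function(zygosity) {
  ifelse(zygosity %in% c("MZm", "MZf"), "MZ", "DZ")
}

#' @export
print.twin_dataset <- function(x, ...) {
  d <- describe_dataset(x)
  cat(sprintf("<twin_dataset> %d families, %d traits (%d continuous, %d ordinal)\n",
              d$n_families, nrow(x$specs),
              sum(x$specs$measure == "continuous"),
              sum(x$specs$measure == "ordinal")))
  cat(sprintf("  %.1f%% male, %.1f%% MZ, age %.1f (SD %.1f, range %.0f-%.0f)\n",
              d$pct_male, d$pct_mz, d$age_mean, d$age_sd, d$age_min, d$age_max))
  invisible(x)
}

#' Descriptive summary of a twin dataset
#'
#' Counts by zygosity group (complete and incomplete pairs), percentage of
#' male and MZ individuals, and the age distribution.
#'
#' @param data A [twin_dataset()].
#' @return List with `n_families`, `n_individuals`, `groups` (data frame of
#'   per-group total/complete pair counts), `pct_male`, `pct_mz`,
#'   `age_mean`, `age_sd`, `age_min`, `age_max`.
#' @export
describe_dataset <- function(data) {
  stopifnot(inherits(data, "twin_dataset"))
  df <- data$data
  if (nrow(df) == 0L) {
    warning("empty dataset")
    return(list(n_families = 0L, n_individuals = 0L,
                groups = data.frame(zygosity = zygosity_groups(),
                                    pairs = 0L, complete = 0L),
                pct_male = NA_real_, pct_mz = NA_real_, age_mean = NA_real_,
                age_sd = NA_real_, age_min = NA_real_, age_max = NA_real_))
  }
  present <- twin_presence(data)
  n_ind <- rowSums(present)
  comp <- rowSums(present) == 2L
  groups <- data.frame(zygosity = zygosity_groups())
  groups$pairs <- vapply(groups$zygosity,
                         function(g) sum(df$zygosity == g), integer(1))
  groups$complete <- vapply(groups$zygosity,
                            function(g) sum(df$zygosity == g & comp), integer(1))
  sex <- c(df$sex1[present[, 1L]], df$sex2[present[, 2L]])
  mz <- relatedness_class(df$zygosity) == "MZ"
  n_mz_ind <- sum(n_ind[mz])
  list(n_families = nrow(df), n_individuals = sum(n_ind), groups = groups,
       pct_male = 100 * mean(sex == 1), pct_mz = 100 * n_mz_ind / sum(n_ind),
       age_mean = mean(df$age), age_sd = stats::sd(df$age),
       age_min = min(df$age), age_max = max(df$age))
}

# n x 2 logical matrix: is twin t present (any non-missing trait value)?
twin_presence <- function(data) {
  df <- data$data
  tr <- data$specs$trait
  p1 <- rowSums(!is.na(df[, paste0(tr, "_1"), drop = FALSE])) > 0
  p2 <- rowSums(!is.na(df[, paste0(tr, "_2"), drop = FALSE])) > 0
  cbind(p1, p2)
}

#' Write a twin dataset as a long-format component-level CSV
#'
#' One row per individual twin, columns `family_id`, `twin` (1/2),
#' `zygosity`, `sex`, `age`, the trait columns, and `global` (sum of the
#' seven component scores when all are present). Twins with no observed
#' traits are omitted.
#'
#' @param data A [twin_dataset()].
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_twin_csv <- function(data, path) {
  stopifnot(inherits(data, "twin_dataset"))
  df <- data$data
  tr <- data$specs$trait
  present <- twin_presence(data)
  one <- function(t) {
    sub <- df[present[, t], , drop = FALSE]
    out <- data.frame(family_id = sub$family_id, twin = t,
                      zygosity = sub$zygosity,
                      sex = if (t == 1L) sub$sex1 else sub$sex2,
                      age = sub$age, stringsAsFactors = FALSE)
    for (v in tr) out[[v]] <- sub[[paste0(v, "_", t)]]
    out
  }
  long <- rbind(one(1L), one(2L))
  long <- long[order(long$family_id, long$twin), ]
  vals <- as.matrix(long[, tr])
  long$global <- ifelse(rowSums(is.na(vals)) == 0, rowSums(vals), NA)
  utils::write.csv(long, path, row.names = FALSE)
  invisible(path)
}

#' Read a long-format component-level CSV into a twin dataset
#'
#' Inverse of [write_twin_csv()]. Families present with a single twin
#' become incomplete pairs.
#'
#' @param path CSV path.
#' @param specs Measurement specification (default [psqi_specs()]).
#' @return A [twin_dataset()].
#' @export
read_twin_csv <- function(path, specs = psqi_specs()) {
  long <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("family_id", "twin", "zygosity", "sex", "age", specs$trait)
  miss <- setdiff(need, names(long))
  if (length(miss))
    stop_input("CSV lacks columns: %s", paste(miss, collapse = ", "))
  fams <- unique(long$family_id)
  rows <- lapply(fams, function(f) {
    sub <- long[long$family_id == f, , drop = FALSE]
    r <- data.frame(family_id = f, zygosity = sub$zygosity[1L],
                    age = sub$age[1L], sex1 = NA_real_, sex2 = NA_real_,
                    stringsAsFactors = FALSE)
    for (v in specs$trait) {
      r[[paste0(v, "_1")]] <- NA_real_
      r[[paste0(v, "_2")]] <- NA_real_
    }
    for (i in seq_len(nrow(sub))) {
      t <- sub$twin[i]
      r[[paste0("sex", t)]] <- sub$sex[i]
      for (v in specs$trait) r[[paste0(v, "_", t)]] <- sub[[v]][i]
    }
    # absent co-twin: impute the sex implied by the zygosity group so the
    # record is usable as a covariate-complete singleton
    if (is.na(r$sex1)) r$sex1 <- default_cotwin_sex(r$zygosity, r$sex2)
    if (is.na(r$sex2)) r$sex2 <- default_cotwin_sex(r$zygosity, r$sex1)
    r
  })
  twin_dataset(do.call(rbind, rows), specs)
}

default_cotwin_sex <- function(zygosity, other_sex) {
  switch(zygosity,
         MZm = 1, DZm = 1, MZf = 0, DZf = 0,
         DOS = 1 - other_sex)
}
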