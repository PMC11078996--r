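## Assembly of the per-oocyte model input table: mask-specific shape
## descriptors, between-region ratios, cohort averages, cohort-relative
## deviations, and the two clinical features.
##
## The natural enumeration gives 48 non-clinical columns (12 descriptors +
## 12 ratios + 12 cohort averages + 12 cohort-relative) plus oocyte age
## and cohort size: 50 in total.  Clinical reports of this feature family
## quote 47 columns without an exact enumeration; the full 50 are kept
## here and a drop list can reproduce any smaller subset.

#' Cohort average of a feature
#'
#' Arithmetic mean over all oocytes sharing a retrieval-cycle cohort,
#' broadcast back to each member row.  Singleton cohorts are allowed.
#'
#' @param x numeric per-oocyte feature values.
#' @param cohort cohort (cycle) identifier per oocyte.
#' @return numeric vector, same length as \code{x}.
#' @export
cohortAverage <- function(x, cohort) {
  if (!length(x)) stop("empty cohort input")
  if (length(x) != length(cohort)) stop("x and cohort must be aligned")
  ave(x, cohort, FUN = mean)
}

#' Cohort-relative deviation of a feature
#'
#' Feature value minus the average over the oocyte's own cohort; negative
#' values mean the oocyte lies below its cohort's average.  Sums to zero
#' exactly within every cohort; singleton cohorts give exactly zero.
#'
#' @inheritParams cohortAverage
#' @return numeric vector of signed deviations.
#' @export
cohortRelative <- function(x, cohort) {
  x - cohortAverage(x, cohort)
}

## the deterministic, documented column enumeration
featureSchemaTable <- function() {
  rows <- list(); k <- 0L
  add <- function(column, group, regions) {
    k <<- k + 1L
    rows[[k]] <<- data.frame(column = column, group = group,
                             regions = regions, stringsAsFactors = FALSE)
  }
  desc <- c("aspect_ratio", "circularity", "roundness", "solidity")
  for (r in REGIONS) for (d in desc)
    add(paste0(r, "_", d), r, r)
  relnames <- character()
  for (pair in REGION_PAIRS) {
    regs <- paste(strsplit(pair, "_vs_")[[1]], collapse = "/")
    for (m in MEASURES) {
      nm <- paste0(pair, "_", m, "_ratio")
      relnames <- c(relnames, nm)
      add(nm, "relative", regs)
    }
  }
  for (nm in relnames) {
    regs <- paste(strsplit(sub("_(major_axis|minor_axis|perimeter|area)_ratio$",
                               "", nm), "_vs_")[[1]], collapse = "/")
    add(paste0("cohort_avg_", nm), "cohort_avg", regs)
  }
  for (nm in relnames)
    add(paste0("cohort_rel_", nm), "cohort_rel",
        paste(strsplit(sub("_(major_axis|minor_axis|perimeter|area)_ratio$",
                           "", nm), "_vs_")[[1]], collapse = "/"))
  add("oocyte_age", "clinical", "")
  add("n_mii_oocytes", "clinical", "")
  do.call(rbind, rows)
}

geometryFromRow <- function(row, region) {
  RegionGeometry(region,
                 area = row[[paste0(region, "_area")]],
                 perimeter = row[[paste0(region, "_perimeter")]],
                 majorAxis = row[[paste0(region, "_major_axis")]],
                 minorAxis = row[[paste0(region, "_minor_axis")]],
                 hullArea = row[[paste0(region, "_hull_area")]])
}

#' Assemble the model input feature table
#'
#' Turns per-oocyte region measurements into the 50-column model input:
#' 12 mask-specific shape descriptors, 12 between-region ratios, their 12
#' cohort averages and 12 cohort-relative deviations (cohort = all MII
#' oocytes of one retrieval cycle, resolved through \code{cycle_id}), and
#' the clinical features \code{oocyte_age} and \code{n_mii_oocytes}.
#' Absolute pixel-valued measurements never enter the table: only
#' dimensionless descriptors and ratios, which generalise across optical
#' setups.
#'
#' Rows with incomplete geometry are rejected with a logged reason rather
#' than propagated as missing values.
#'
#' @param data an [OocyteStudy-class] or a data.frame carrying the id
#'   columns (\code{oocyte_id, patient_id, cycle_id, clinic}),
#'   \code{oocyte_age}, \code{n_mii_oocytes}, \code{outcome} and the
#'   region measurement columns produced by [measureOocyte()].
#' @param dropColumns optional character vector of feature columns to
#'   exclude (for reproducing smaller published enumerations).
#' @return an [OocyteFeatureSet-class].
#' @export
assembleFeatureTable <- function(data, dropColumns = character()) {
  if (is(data, "OocyteStudy")) data <- data@oocytes
  need <- c("oocyte_id", "patient_id", "cycle_id", "clinic",
            "oocyte_age", "n_mii_oocytes", "outcome")
  miss <- setdiff(need, colnames(data))
  if (length(miss))
    stop("missing metadata columns: ", paste(miss, collapse = ", "))
  geomCols <- as.vector(outer(REGIONS, c("area", "perimeter", "major_axis",
                                         "minor_axis", "hull_area"),
                              function(r, m) paste0(r, "_", m)))
  miss <- setdiff(geomCols, colnames(data))
  if (length(miss))
    stop("missing geometry columns: ", paste(miss, collapse = ", "))
  ok <- stats::complete.cases(data[, geomCols])
  if (any(!ok)) {
    message(sum(!ok), " oocyte(s) rejected: incomplete region geometry (",
            paste(utils::head(data$oocyte_id[!ok], 5), collapse = ", "), ")")
    data <- data[ok, , drop = FALSE]
  }
  if (!nrow(data)) stop("no oocytes with complete geometry")

  feats <- data.frame(row.names = data$oocyte_id)
  for (r in REGIONS) {
    sd4 <- t(vapply(seq_len(nrow(data)), function(i)
      shapeDescriptors(geometryFromRow(data[i, ], r)), numeric(4)))
    colnames(sd4) <- paste0(r, "_", c("aspect_ratio", "circularity",
                                      "roundness", "solidity"))
    feats <- cbind(feats, as.data.frame(sd4))
  }
  rel <- t(vapply(seq_len(nrow(data)), function(i) {
    geoms <- lapply(REGIONS, function(r) geometryFromRow(data[i, ], r))
    names(geoms) <- REGIONS
    relativeFeatures(geoms)
  }, numeric(12)))
  feats <- cbind(feats, as.data.frame(rel))
  relnames <- colnames(rel)
  for (nm in relnames)
    feats[[paste0("cohort_avg_", nm)]] <- cohortAverage(feats[[nm]], data$cycle_id)
  for (nm in relnames)
    feats[[paste0("cohort_rel_", nm)]] <- cohortRelative(feats[[nm]], data$cycle_id)
  feats$oocyte_age <- as.numeric(data$oocyte_age)
  feats$n_mii_oocytes <- as.numeric(data$n_mii_oocytes)

  schema <- featureSchemaTable()
  if (length(dropColumns)) {
    unknown <- setdiff(dropColumns, schema$column)
    if (length(unknown))
      stop("unknown feature columns in dropColumns: ",
           paste(unknown, collapse = ", "))
    schema <- schema[!schema$column %in% dropColumns, , drop = FALSE]
    feats <- feats[, schema$column, drop = FALSE]
  } else {
    feats <- feats[, schema$column, drop = FALSE]
  }
  meta <- data.frame(oocyte_id = data$oocyte_id,
                     patient_id = data$patient_id,
                     cycle_id = data$cycle_id,
                     clinic = data$clinic,
                     outcome = as.integer(data$outcome),
                     stringsAsFactors = FALSE,
                     row.names = data$oocyte_id)
  ## cohort-relative columns must average to zero within every cohort at
  ## assembly time (later row subsetting keeps cycles intact only when
  ## done at the patient level, so the check lives here)
  for (cc in schema$column[schema$group == "cohort_rel"]) {
    if (max(abs(ave(feats[[cc]], meta$cycle_id, FUN = mean))) > 1e-8)
      stop("internal error: cohort-relative column ", cc,
           " does not average to zero within cohorts")
  }
  new("OocyteFeatureSet", features = feats, schema = schema, meta = meta)
}

#' Accessors for OocyteFeatureSet
#'
#' @param fs an [OocyteFeatureSet-class].
#' @return \code{featureMatrix}: numeric matrix of features;
#'   \code{featureSchema}: the column/group/regions schema;
#'   \code{outcomeLabels}: integer 0/1 outcomes; \code{sampleInfo}: the
#'   per-oocyte metadata.
#' @export
featureMatrix <- function(fs) {
  stopifnot(is(fs, "OocyteFeatureSet"))
  as.matrix(fs@features)
}

#' @rdname featureMatrix
#' @export
featureSchema <- function(fs) {
  stopifnot(is(fs, "OocyteFeatureSet"))
  fs@schema
}

#' @rdname featureMatrix
#' @export
outcomeLabels <- function(fs) {
  stopifnot(is(fs, "OocyteFeatureSet"))
  fs@meta$outcome
}

#' @rdname featureMatrix
#' @export
sampleInfo <- function(fs) {
  stopifnot(is(fs, "OocyteFeatureSet"))
  fs@meta
}

#' Drop named feature groups from a feature set
#'
#' Region groups (\code{"ooplasm"}, \code{"pvs"}, \code{"zp"}) remove the
#' region's own descriptors plus every relative / cohort column involving
#' that region; \code{"clinical"} removes the two clinical columns;
#' \code{"cohort"} removes all cohort averages and cohort-relative
#' columns; \code{"relative"} removes the 12 plain between-region ratios.
#' Used by [ablationEval()] to quantify each group's contribution.
#'
#' @param fs an [OocyteFeatureSet-class].
#' @param groups character vector of group labels.
#' @return a reduced [OocyteFeatureSet-class].
#' @export
dropFeatureGroups <- function(fs, groups) {
  stopifnot(is(fs, "OocyteFeatureSet"))
  known <- c(REGIONS, "clinical", "cohort", "relative", "cohort_avg", "cohort_rel")
  bad <- setdiff(groups, known)
  if (length(bad)) stop("unknown feature groups: ", paste(bad, collapse = ", "))
  sch <- fs@schema
  drop <- rep(FALSE, nrow(sch))
  for (g in groups) {
    drop <- drop | switch(g,
      ooplasm = , pvs = , zp =
        vapply(strsplit(sch$regions, "/"), function(r) g %in% r, logical(1)),
      clinical = sch$group == "clinical",
      cohort = sch$group %in% c("cohort_avg", "cohort_rel"),
      cohort_avg = sch$group == "cohort_avg",
      cohort_rel = sch$group == "cohort_rel",
      relative = sch$group == "relative")
  }
  if (all(drop)) stop("cannot drop every feature column")
  new("OocyteFeatureSet",
      features = fs@features[, sch$column[!drop], drop = FALSE],
      schema = sch[!drop, , drop = FALSE],
      meta = fs@meta)
}

#' @describeIn OocyteFeatureSet-class compact display
#' @param object an OocyteFeatureSet
#' @export
setMethod("show", "OocyteFeatureSet", function(object) {
  cat("OocyteFeatureSet:", nrow(object@features), "oocytes x",
      ncol(object@features), "features\n")
  tab <- table(object@schema$group)
  cat("  groups:", paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
  cat("  prevalence:", round(mean(object@meta$outcome), 3), "\n")
})

#' Subset a feature set by row
#' @param x an [OocyteFeatureSet-class]
#' @param i row index vector
#' @param j unused
#' @param drop unused
#' @param ... unused
#' @export
setMethod("[", "OocyteFeatureSet", function(x, i, j, ..., drop = FALSE) {
  new("OocyteFeatureSet", features = x@features[i, , drop = FALSE],
      schema = x@schema, meta = x@meta[i, , drop = FALSE])
})
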