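fmtNum <- function(x) sprintf("%.17g", x)  # lossless double round-trip

#' Write / read a cohort as plain-text tables
#'
#' Serializes a cohort to a directory of delimited text files:
#' \code{cells/<patient>.csv} (cell_id, x_um, y_um, phenotype),
#' \code{clinical.csv} (patient_id, er, pr, her2, grade; receptors as
#' pos/neg), \code{survival.csv} (patient_id, os_months, event),
#' \code{palette.json} and, when ground truth is present,
#' \code{ground_truth.json}. \code{readCohort} validates every schema and
#' reports the offending file and column on failure; receptor status is
#' parsed back to binary flags. The pair round-trips a generated cohort.
#'
#' @param cohort a cohort list as returned by \code{\link{generateCohort}}
#'   (ground truth optional).
#' @param dir directory to write to / read from.
#' @return \code{writeCohort}: the directory, invisibly.
#'   \code{readCohort}: a cohort list (\code{images}, \code{clinical},
#'   \code{survival}, \code{palette}, and \code{truth} if stored).
#' @export
writeCohort <- function(cohort, dir) {
  dir.create(file.path(dir, "cells"), recursive = TRUE, showWarnings = FALSE)
  for (img in cohort$images) {
    tab <- img@cells
    out <- data.frame(cell_id = tab$cell_id, x_um = fmtNum(tab$x_um),
                      y_um = fmtNum(tab$y_um), phenotype = tab$phenotype)
    write.csv(out, file.path(dir, "cells", paste0(img@patientId, ".csv")),
              row.names = FALSE, quote = FALSE)
  }
  meta <- data.frame(
    patient_id = vapply(cohort$images, slot, "", "patientId"),
    area_um2 = fmtNum(vapply(cohort$images, slot, 0, "areaUm2")),
    neighbor_radius = fmtNum(vapply(cohort$images, slot, 0, "neighborRadius")))
  write.csv(meta, file.path(dir, "images.csv"), row.names = FALSE, quote = FALSE)

  cl <- cohort$clinical
  write.csv(data.frame(patient_id = cl$patient_id,
                       er = ifelse(cl$er == 1, "pos", "neg"),
                       pr = ifelse(cl$pr == 1, "pos", "neg"),
                       her2 = ifelse(cl$her2 == 1, "pos", "neg"),
                       grade = cl$grade),
            file.path(dir, "clinical.csv"), row.names = FALSE, quote = FALSE)

  y <- cohort$survival
  write.csv(data.frame(patient_id = y@patientId,
                       os_months = fmtNum(y@time), event = y@event),
            file.path(dir, "survival.csv"), row.names = FALSE, quote = FALSE)

  pal <- cohort$palette
  jsonlite::write_json(list(phenotypes = phenotypes(pal),
                            classes = as.list(phenotypeClass(pal))),
                       file.path(dir, "palette.json"), auto_unbox = TRUE)
  if (!is.null(cohort$truth)) {
    tr <- cohort$truth
    jsonlite::write_json(
      list(subtype_of = as.list(tr$subtypeOf),
           true_effects = as.list(tr$trueEffects),
           true_linear_predictor = as.list(tr$trueLinearPredictor),
           true_features = list(names = rownames(tr$trueFeatures),
                                patients = colnames(tr$trueFeatures),
                                values = tr$trueFeatures)),
      file.path(dir, "ground_truth.json"), auto_unbox = TRUE, digits = NA)
  }
  invisible(dir)
}

requireCols <- function(tab, cols, file) {
  miss <- setdiff(cols, names(tab))
  if (length(miss))
    stop("malformed table ", file, ": missing column(s) ",
         paste(miss, collapse = ", "), call. = FALSE)
}

parseFlag <- function(x, file, col) {
  if (is.numeric(x)) {
    if (!all(x %in% c(0, 1))) stop("malformed table ", file, ": column ", col,
                                   " must be pos/neg or 0/1", call. = FALSE)
    return(as.integer(x))
  }
  v <- tolower(trimws(as.character(x)))
  bad <- which(!v %in% c("pos", "neg", "positive", "negative", "1", "0"))
  if (length(bad))
    stop("malformed table ", file, ": column ", col, ", line ", bad[1] + 1L,
         ": unrecognized value '", x[bad[1]], "'", call. = FALSE)
  as.integer(v %in% c("pos", "positive", "1"))
}

#' @rdname writeCohort
#' @export
readCohort <- function(dir) {
  palPath <- file.path(dir, "palette.json")
  if (!file.exists(palPath)) stop("missing palette.json in ", dir)
  pj <- jsonlite::read_json(palPath, simplifyVector = TRUE)
  pal <- PhenotypePalette(pj$phenotypes, unlist(pj$classes))

  metaFile <- file.path(dir, "images.csv")
  meta <- read.csv(metaFile, stringsAsFactors = FALSE)
  requireCols(meta, c("patient_id", "area_um2", "neighbor_radius"), metaFile)

  images <- lapply(seq_len(nrow(meta)), function(i) {
    f <- file.path(dir, "cells", paste0(meta$patient_id[i], ".csv"))
    if (!file.exists(f)) stop("missing cell table ", f, call. = FALSE)
    tab <- read.csv(f, stringsAsFactors = FALSE)
    requireCols(tab, c("cell_id", "x_um", "y_um", "phenotype"), f)
    if (anyNA(tab$x_um) || anyNA(tab$y_um)) {
      bad <- which(is.na(tab$x_um) | is.na(tab$y_um))[1]
      stop("malformed table ", f, ": non-numeric coordinate at line ",
           bad + 1L, call. = FALSE)
    }
    unknown <- setdiff(unique(tab$phenotype), phenotypes(pal))
    if (length(unknown))
      stop("malformed table ", f, ": phenotype(s) not in palette: ",
           paste(unknown, collapse = ", "), call. = FALSE)
    PatientImage(meta$patient_id[i], tab, areaUm2 = meta$area_um2[i],
                 neighborRadius = meta$neighbor_radius[i])
  })
  names(images) <- meta$patient_id

  clFile <- file.path(dir, "clinical.csv")
  cl <- read.csv(clFile, stringsAsFactors = FALSE)
  requireCols(cl, c("patient_id", "er", "pr", "her2", "grade"), clFile)
  clinical <- data.frame(patient_id = as.character(cl$patient_id),
                         er = parseFlag(cl$er, clFile, "er"),
                         pr = parseFlag(cl$pr, clFile, "pr"),
                         her2 = parseFlag(cl$her2, clFile, "her2"),
                         grade = as.integer(cl$grade),
                         stringsAsFactors = FALSE)

  svFile <- file.path(dir, "survival.csv")
  sv <- read.csv(svFile, stringsAsFactors = FALSE)
  requireCols(sv, c("patient_id", "os_months", "event"), svFile)
  surv <- SurvivalOutcome(sv$patient_id, sv$os_months, sv$event)

  truth <- NULL
  gtPath <- file.path(dir, "ground_truth.json")
  if (file.exists(gtPath)) {
    gt <- jsonlite::read_json(gtPath, simplifyVector = TRUE)
    tf <- gt$true_features
    truthFeatures <- matrix(unlist(tf$values), nrow = length(tf$names),
                            dimnames = list(tf$names, tf$patients))
    truth <- list(subtypeOf = unlist(gt$subtype_of),
                  trueEffects = unlist(gt$true_effects),
                  trueFeatures = truthFeatures,
                  trueLinearPredictor = unlist(gt$true_linear_predictor))
  }
  list(images = images, clinical = clinical, survival = surv,
       truth = truth, palette = pal)
}
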