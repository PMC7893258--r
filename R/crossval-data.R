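#' Published cross-validation table: 21 whales with both channels
#'
#' The 21 tagged humpback whales (Canada and Norway feeding grounds) for
#' which both body-condition channels were published: the tag-derived
#' tissue body density posterior (mean and sd, kg m^-3, from the glide
#' model), the combined drag term (posterior mean and sd, 1e-6 m^2
#' kg^-1), and the LSSAI from overhead photogrammetry. These whales
#' anchor the cross-validation of the two methods (their TBD and LSSAI
#' correlate at r = -0.48) and serve as the observed calibration range
#' for the synthetic generators.
#'
#' @return tibble with columns `tag_id, whale_id, date, location,
#'   age_class, sex, pregnant, lactating, n_glides, tbd_mean, tbd_sd,
#'   drag_mean_e6, drag_sd_e6, lssai`.
#' @export
crossvalTable <- function() {
  tibble::tibble(
    tag_id = c("Mn16_175a", "Mn16_178a", "Mn16_250a", "Mn16_258a",
               "Mn17_022a", "Mn17_026LLa", "Mn17_026a", "Mn17_158a",
               "Mn17_165a", "Mn17_174a", "Mn17_174b", "Mn17_178a",
               "Mn17_178c", "Mn17_180a", "Mn17_180b", "Mn17_184a",
               "Mn17_186b", "Mn17_186c", "Mn17_186d", "Mn17_190a",
               "Mn18_013a"),
    whale_id = c("H140", "HAN", "H494", "H109", "HW1", "HW7", "HW8",
                 "FOF", "H102", "H456", "H854", "H748", "H008", "H007",
                 "H777", "EYE", "H152", "H151", "FOS", "H584", "ROL"),
    date = as.Date(c("2016-06-23", "2016-06-29", "2016-09-06", "2016-09-14",
                     "2017-01-22", "2017-01-26", "2017-01-25", "2017-06-06",
                     "2017-06-12", "2017-06-21", "2017-06-21", "2017-06-25",
                     "2017-06-24", "2017-06-27", "2017-06-29", "2017-07-03",
                     "2017-07-05", "2017-07-05", "2017-07-05", "2017-07-07",
                     "2018-01-13")),
    location = c(rep("Canada", 4), rep("Norway", 3), rep("Canada", 13),
                 "Norway"),
    age_class = c("adult", "juvenile", "adult", "adult", "adult", "adult",
                  "adult", "adult", "adult", "adult", "adult", "adult",
                  "adult", "adult", "adult", "adult", "adult", "adult",
                  "adult", "adult", "juvenile"),
    sex = c("female", "female", "female", "female", "female", "female",
            "unknown", "female", "female", "female", "male", "female",
            "female", "male", "female", "female", "male", "male",
            "female", "female", "female"),
    pregnant = c(0, 0, 0, 0, 1, 1, 0, 0, 1, 1, 0, 1, 0, 0, 0, 0, 0, 0,
                 0, 0, 0),
    lactating = c(0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0, 0,
                  0, 1, 0),
    n_glides = c(88L, 10L, 28L, 49L, 35L, 14L, 84L, 83L, 131L, 177L,
                 69L, 208L, 215L, 133L, 92L, 103L, 101L, 134L, 68L,
                 277L, 41L),
    tbd_mean = c(1032.9, 1043.0, 1036.8, 1028.8, 1029.1, 1033.9, 1035.4,
                 1030.6, 1032.5, 1034.0, 1035.2, 1035.0, 1041.3, 1037.1,
                 1043.6, 1038.6, 1038.8, 1037.6, 1031.8, 1035.7, 1042.0),
    tbd_sd = c(1.6, 8.4, 4.7, 3.2, 1.2, 3.5, 1.2, 1.8, 2.2, 1.5, 2.9,
               1.4, 2.1, 2.2, 2.9, 2.6, 3.0, 2.0, 2.2, 1.7, 1.7),
    drag_mean_e6 = c(10.1, 17.5, 15.7, 16.1, 10.8, 4.3, 7.6, 8.2, 4.0,
                     20.7, 11.7, 20.4, 1.6, 16.0, 20.5, 17.9, 6.1, 10.1,
                     20.3, 14.4, 15.3),
    drag_sd_e6 = c(4.2, 12.3, 4.6, 6.4, 3.5, 6.7, 2.5, 4.5, 6.0, 4.3,
                   6.1, 2.1, 3.7, 3.5, 3.9, 3.9, 4.5, 3.4, 4.6, 2.6,
                   2.5),
    lssai = c(0.07180, 0.06629, 0.07924, 0.09396, 0.08181, 0.08713,
              0.07129, 0.08463, 0.07817, 0.07148, 0.07194, 0.07907,
              0.06810, 0.06968, 0.07399, 0.06846, 0.06706, 0.07619,
              0.07021, 0.06477, 0.08406)
  )
}

#' Cross-validation table as fusion-model whale records
#'
#' Reshapes [crossvalTable()] into the [whaleRecords()] schema (season
#' day from date and location, immature from age class, dual observation
#' channels).
#'
#' @return a validated whale-records tibble (21 rows).
#' @export
crossvalRecords <- function() {
  tb <- crossvalTable()
  whaleRecords(tibble::tibble(
    whale_id = tb$tag_id,
    location = tb$location,
    season_day = seasonDay(tb$date, tb$location),
    sex = tb$sex,
    pregnant = tb$pregnant,
    lactating = tb$lactating,
    immature = as.integer(tb$age_class == "juvenile"),
    tbd_mean = tb$tbd_mean,
    tbd_sd = tb$tbd_sd,
    lssai = tb$lssai
  ))
}
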