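#!/usr/bin/env Rscript
# Stage 2: reduce weekly reports to the monthly panel.
#
# For each child-month the response is the sum of reported sessions divided
# by the number of answered weeks; months with two or fewer answers are
# missing, and children with fewer than two calculated months are excluded
# from the trajectory analysis.

library(sporttraj)

data_dir <- "results/data"
weekly <- read.csv(file.path(data_dir, "weekly_responses.csv"))
roster <- read.csv(file.path(data_dir, "roster.csv"))
roster$dob <- as.Date(roster$dob)
roster$entry_month <- as.Date(roster$entry_month)
roster$exit_month <- as.Date(roster$exit_month)

calendar <- build_study_calendar("2009-08-01", "2014-06-30")
panel_all <- aggregate_weekly_to_monthly(weekly, calendar, roster)
ex <- exclude_sparse_children(panel_all)

write.csv(ex$panel, file.path(data_dir, "monthly_panel.csv"),
          row.names = FALSE)

cat("Monthly panel:", nrow(ex$panel), "child-months,",
    length(unique(ex$panel$child_id)), "children",
    sprintf("(%d excluded as too sparse).\n", length(ex$excluded)))
cat(sprintf("Missing months: %.1f%%; observed y in [%.2f, %.2f].\n",
            100 * mean(is.na(ex$panel$y)),
            min(ex$panel$y, na.rm = TRUE), max(ex$panel$y, na.rm = TRUE)))
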