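# Provenance notes for the packaged re-irradiation dataset

The two CSVs in this directory are a study-level transcription of published
thoracic re-irradiation reports (21 studies, 505 patients, data collected
1996-2017). Study labels are the first author of each source report.

`reirradiation_studies.csv` — one row per study: number of patients (`n`),
grouped count of grade >=3 oesophageal toxicity events (`events`), the study's
representative (median) cumulative oesophageal maximal dose in EQD2 Gy
(`cdmax_rep_gy_eqd2`), fraction of patients receiving concurrent chemotherapy
with re-irradiation (`chemo_fraction`), median interval between courses in
months (`interval_rep_months`) and median follow-up after re-irradiation
(`followup_rep_months`). "NR" = not recorded in the source report, stored as
missing, never as zero.

`toxicity_events.csv` — one row per (study, timing, grade, category) cell of
the reported grade >=3 event descriptions. Raw event rows sum to 57; eight
patients experienced both an acute (within 3 months) and a late event, so the
per-patient grouped totals in `reirradiation_studies.csv` sum to 49.

Transcription conventions and known discrepancies:

- Grouped per-study event counts are taken from the itemised event
  descriptions where a study reports them; otherwise computed as
  round(n x toxicity% / 100) from the study-level toxicity rate. Where the
  two disagree, the itemised integer counts win:
  - Schlampp: 4.8% of 62 = 2.98 (~3), but 2 itemised events (late stenosis
    G3, late tracheo-oesophageal fistula G4); stored as 2.
  - Katano: 16.7% of 4 = 0.67, but 1 itemised event; stored as 1.
- One study (Chen) grouped grade 2-4 toxicity together in its source report,
  so a small share of its 19 acute G3 oesophagitis/dysphagia events may be
  grade 2; counts are stored as printed.
- Chen's 7 late G4 "haemorrhage / tracheo-oesophageal fistula" events are
  categorised as perforation_tof, the only assignment consistent with the
  source's category totals (perforation/TOF 30, oesophagitis/dysphagia 23,
  bleeding 2, stenosis 2).
- Doses are stored as printed; several source studies quoted D1cc rather
  than D_max, or a slightly different alpha/beta ratio, and are not
  harmonised (the effect is to underestimate the delivered D_max).
- The 144-patient individual-level validation subset of the source analysis
  is not printed patient-by-patient and cannot be reconstructed here; the
  `builtin_fixture()` pseudo-patient expansion assigns every patient the
  study median dose and is clearly flagged as reconstructed.
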