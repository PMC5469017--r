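# Co-occurrence pattern rules for measurement-value linking (38 rules).
# Columns: rule_id,priority,slots,sep_class,sep_regex,value_kind,is_range,unit_mode,max_gap,scope
#   slots      : slot sequence; one TERM (or TERM_HEAD/TERM_TAIL) and one VALUE per rule
#   sep_class  : named separator class; sep_regex is matched against the full
#                text between the TERM and VALUE slots (anchored by the engine)
#   value_kind : QUANT or QUAL
#   is_range   : whether the VALUE slot must be a range mention
#   unit_mode  : attached (unit inside VALUE), detached (trailing UNIT slot),
#                absent (no unit)
#   max_gap    : maximum characters between consecutive slots
#   scope      : LINE (semi-structured) or SENTENCE (narrative)
eq_att_pt,1,TERM SEP VALUE,equals,\s*=\s*,QUANT,FALSE,attached,40,LINE
eq_att_rg,2,TERM SEP VALUE,equals,\s*=\s*,QUANT,TRUE,attached,40,LINE
eq_det_pt,3,TERM SEP VALUE UNIT,equals,\s*=\s*,QUANT,FALSE,detached,40,LINE
eq_det_rg,4,TERM SEP VALUE UNIT,equals,\s*=\s*,QUANT,TRUE,detached,40,LINE
eq_abs_pt,5,TERM SEP VALUE,equals,\s*=\s*,QUANT,FALSE,absent,40,LINE
eq_abs_rg,6,TERM SEP VALUE,equals,\s*=\s*,QUANT,TRUE,absent,40,LINE
col_att_pt,7,TERM SEP VALUE,colon,\s*:\s*,QUANT,FALSE,attached,40,LINE
col_att_rg,8,TERM SEP VALUE,colon,\s*:\s*,QUANT,TRUE,attached,40,LINE
col_det_pt,9,TERM SEP VALUE UNIT,colon,\s*:\s*,QUANT,FALSE,detached,40,LINE
col_det_rg,10,TERM SEP VALUE UNIT,colon,\s*:\s*,QUANT,TRUE,detached,40,LINE
col_abs_pt,11,TERM SEP VALUE,colon,\s*:\s*,QUANT,FALSE,absent,40,LINE
col_abs_rg,12,TERM SEP VALUE,colon,\s*:\s*,QUANT,TRUE,absent,40,LINE
paren_att_pt,13,TERM SEP VALUE,lparen,\s*\(\s*,QUANT,FALSE,attached,10,LINE
paren_att_rg,14,TERM SEP VALUE,lparen,\s*\(\s*,QUANT,TRUE,attached,10,LINE
mv_att_pt,15,TERM SEP VALUE,measure_verb,\s+(?:is|was)\s+(?:visually\s+)?(?:measured|estimated|calculated|noted)\s+(?:at|as|to\s+be|in\s+a\s+range\s+of)\s+,QUANT,FALSE,attached,48,SENTENCE
mv_att_rg,16,TERM SEP VALUE,measure_verb,\s+(?:is|was)\s+(?:visually\s+)?(?:measured|estimated|calculated|noted)\s+(?:at|as|to\s+be|in\s+a\s+range\s+of)\s+,QUANT,TRUE,attached,48,SENTENCE
mv_det_pt,17,TERM SEP VALUE UNIT,measure_verb,\s+(?:is|was)\s+(?:visually\s+)?(?:measured|estimated|calculated|noted)\s+(?:at|as|to\s+be|in\s+a\s+range\s+of)\s+,QUANT,FALSE,detached,48,SENTENCE
mv_det_rg,18,TERM SEP VALUE UNIT,measure_verb,\s+(?:is|was)\s+(?:visually\s+)?(?:measured|estimated|calculated|noted)\s+(?:at|as|to\s+be|in\s+a\s+range\s+of)\s+,QUANT,TRUE,detached,48,SENTENCE
mv_abs_pt,19,TERM SEP VALUE,measure_verb,\s+(?:is|was)\s+(?:visually\s+)?(?:measured|estimated|calculated|noted)\s+(?:at|as|to\s+be|in\s+a\s+range\s+of)\s+,QUANT,FALSE,absent,48,SENTENCE
mv_abs_rg,20,TERM SEP VALUE,measure_verb,\s+(?:is|was)\s+(?:visually\s+)?(?:measured|estimated|calculated|noted)\s+(?:at|as|to\s+be|in\s+a\s+range\s+of)\s+,QUANT,TRUE,absent,48,SENTENCE
cop_att_pt,21,TERM SEP VALUE,copula,\s+(?:is|was|are|were|appears|remains)\s+,QUANT,FALSE,attached,40,SENTENCE
cop_att_rg,22,TERM SEP VALUE,copula,\s+(?:is|was|are|were|appears|remains)\s+,QUANT,TRUE,attached,40,SENTENCE
cop_det_pt,23,TERM SEP VALUE UNIT,copula,\s+(?:is|was|are|were|appears|remains)\s+,QUANT,FALSE,detached,40,SENTENCE
cop_det_rg,24,TERM SEP VALUE UNIT,copula,\s+(?:is|was|are|were|appears|remains)\s+,QUANT,TRUE,detached,40,SENTENCE
cop_abs_pt,25,TERM SEP VALUE,copula,\s+(?:is|was|are|were|appears|remains)\s+,QUANT,FALSE,absent,40,SENTENCE
cop_abs_rg,26,TERM SEP VALUE,copula,\s+(?:is|was|are|were|appears|remains)\s+,QUANT,TRUE,absent,40,SENTENCE
bare_att_pt,27,TERM SEP VALUE,bare,[ \t]+,QUANT,FALSE,attached,20,LINE
bare_att_rg,28,TERM SEP VALUE,bare,[ \t]+,QUANT,TRUE,attached,20,LINE
bare_det_pt,29,TERM SEP VALUE UNIT,bare,[ \t]+,QUANT,FALSE,detached,20,LINE
q_eq_pt,30,TERM SEP VALUE,equals,\s*=\s*,QUAL,FALSE,absent,40,LINE
q_eq_rg,31,TERM SEP VALUE,equals,\s*=\s*,QUAL,TRUE,absent,40,LINE
q_col_pt,32,TERM SEP VALUE,colon,\s*:\s*,QUAL,FALSE,absent,40,LINE
q_col_rg,33,TERM SEP VALUE,colon,\s*:\s*,QUAL,TRUE,absent,40,LINE
q_cop_pt,34,TERM SEP VALUE,copula,\s+(?:is|was|are|were|appears|remains)\s+,QUAL,FALSE,absent,40,SENTENCE
q_cop_rg,35,TERM SEP VALUE,copula,\s+(?:is|was|are|were|appears|remains)\s+,QUAL,TRUE,absent,40,SENTENCE
q_pre_pt,36,VALUE TERM,adjacency,\s+,QUAL,FALSE,absent,3,SENTENCE
q_pre_rg,37,VALUE TERM,adjacency,\s+,QUAL,TRUE,absent,3,SENTENCE
q_within_pt,38,TERM_HEAD VALUE TERM_TAIL,within,\s+,QUAL,FALSE,absent,12,SENTENCE
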