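TABLE_CD,COLUMN_CD,LOCAL_IN_CD,FHIR_OUT_CD,FHIR_SYSTEM
LAB_RESULT_CM,RESULT_MODIFIER,LT,<,http://hl7.org/fhir/quantity-comparator
LAB_RESULT_CM,RESULT_MODIFIER,LE,<=,http://hl7.org/fhir/quantity-comparator
LAB_RESULT_CM,RESULT_MODIFIER,GT,>,http://hl7.org/fhir/quantity-comparator
LAB_RESULT_CM,RESULT_MODIFIER,GE,>=,http://hl7.org/fhir/quantity-comparator
LAB_RESULT_CM,ABN_IND,AB,A,http://hl7.org/fhir/ValueSet/observation-interpretation
LAB_RESULT_CM,ABN_IND,AH,H,http://hl7.org/fhir/ValueSet/observation-interpretation
LAB_RESULT_CM,ABN_IND,AL,L,http://hl7.org/fhir/ValueSet/observation-interpretation
LAB_RESULT_CM,ABN_IND,CH,HH,http://hl7.org/fhir/ValueSet/observation-interpretation
LAB_RESULT_CM,ABN_IND,CL,LL,http://hl7.org/fhir/ValueSet/observation-interpretation
LAB_RESULT_CM,ABN_IND,CR,AA,http://hl7.org/fhir/ValueSet/observation-interpretation
LAB_RESULT_CM,ABN_IND,IN,N,http://hl7.org/fhir/ValueSet/observation-interpretation
ENCOUNTER,ENC_TYPE,AV,AMB,https://hl7.org/fhir/STU3/v3/ActEncounterCode/vs.html
ENCOUNTER,ENC_TYPE,ED,EMER,https://hl7.org/fhir/STU3/v3/ActEncounterCode/vs.html
ENCOUNTER,ENC_TYPE,IP,IMP,https://hl7.org/fhir/STU3/v3/ActEncounterCode/vs.html
ENCOUNTER,ENC_TYPE,IS,NONAC,https://hl7.org/fhir/STU3/v3/ActEncounterCode/vs.html
ENCOUNTER,ENC_TYPE,OS,OBSENC,https://hl7.org/fhir/STU3/v3/ActEncounterCode/vs.html
ENCOUNTER,DISCHARGE_STATUS,HO,home,http://hl7.org/fhir/discharge-disposition
ENCOUNTER,DISCHARGE_STATUS,AL,alt-home,http://hl7.org/fhir/discharge-disposition
ENCOUNTER,DISCHARGE_STATUS,AM,aadvice,http://hl7.org/fhir/discharge-disposition
ENCOUNTER,DISCHARGE_STATUS,EX,exp,http://hl7.org/fhir/discharge-disposition
ENCOUNTER,DISCHARGE_STATUS,HS,hosp,http://hl7.org/fhir/discharge-disposition
ENCOUNTER,DISCHARGE_STATUS,IP,other-hcf,http://hl7.org/fhir/discharge-disposition
ENCOUNTER,DISCHARGE_STATUS,NH,long,http://hl7.org/fhir/discharge-disposition
ENCOUNTER,DISCHARGE_STATUS,RH,rehab,http://hl7.org/fhir/discharge-disposition
ENCOUNTER,DISCHARGE_STATUS,SH,psy,http://hl7.org/fhir/discharge-disposition
ENCOUNTER,DISCHARGE_STATUS,SN,snf,http://hl7.org/fhir/discharge-disposition
ENCOUNTER,DISCHARGE_STATUS,AF,oth,http://hl7.org/fhir/discharge-disposition
ENCOUNTER,ADMITTING_SOURCE,ED,emd,http://hl7.org/fhir/admit-source
ENCOUNTER,ADMITTING_SOURCE,AV,outp,http://hl7.org/fhir/admit-source
ENCOUNTER,ADMITTING_SOURCE,IP,hosp-trans,http://hl7.org/fhir/admit-source
ENCOUNTER,ADMITTING_SOURCE,IH,hosp-trans,http://hl7.org/fhir/admit-source
ENCOUNTER,ADMITTING_SOURCE,NH,nursing,http://hl7.org/fhir/admit-source
ENCOUNTER,ADMITTING_SOURCE,SN,nursing,http://hl7.org/fhir/admit-source
ENCOUNTER,ADMITTING_SOURCE,RH,rehab,http://hl7.org/fhir/admit-source
ENCOUNTER,ADMITTING_SOURCE,AF,other,http://hl7.org/fhir/admit-source
ENCOUNTER,ADMITTING_SOURCE,AL,other,http://hl7.org/fhir/admit-source
ENCOUNTER,ADMITTING_SOURCE,HH,other,http://hl7.org/fhir/admit-source
ENCOUNTER,ADMITTING_SOURCE,HO,other,http://hl7.org/fhir/admit-source
ENCOUNTER,ADMITTING_SOURCE,HS,other,http://hl7.org/fhir/admit-source
ENCOUNTER,ADMITTING_SOURCE,RS,other,http://hl7.org/fhir/admit-source
DEMOGRAPHIC,SEX,M,male,http://hl7.org/fhir/administrative-gender
DEMOGRAPHIC,SEX,F,female,http://hl7.org/fhir/administrative-gender
DEMOGRAPHIC,SEX,A,other,http://hl7.org/fhir/administrative-gender
DEMOGRAPHIC,RACE,01,1002-5,urn:oid:2.16.840.1.113883.6.238
DEMOGRAPHIC,RACE,02,2028-9,urn:oid:2.16.840.1.113883.6.238
DEMOGRAPHIC,RACE,03,2054-5,urn:oid:2.16.840.1.113883.6.238
DEMOGRAPHIC,RACE,04,2076-8,urn:oid:2.16.840.1.113883.6.238
DEMOGRAPHIC,RACE,05,2106-3,urn:oid:2.16.840.1.113883.6.238
DEMOGRAPHIC,HISPANIC,Y,2135-2,urn:oid:2.16.840.1.113883.6.238
DEMOGRAPHIC,HISPANIC,N,2186-5,urn:oid:2.16.840.1.113883.6.238
VITAL,SMOKING,01,449868002,http://snomed.info/sct
VITAL,SMOKING,02,428041000124106,http://snomed.info/sct
VITAL,SMOKING,03,8517006,http://snomed.info/sct
VITAL,SMOKING,04,266919005,http://snomed.info/sct
VITAL,SMOKING,05,77176002,http://snomed.info/sct
VITAL,SMOKING,06,266927001,http://snomed.info/sct
VITAL,SMOKING,07,428071000124103,http://snomed.info/sct
VITAL,SMOKING,08,428061000124105,http://snomed.info/sct
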