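Input: If today was 2013-05-02, what would the date of "yesterday" be?
Output: 2013-05-01

Input: If today was 2022-04-29, what would the date of "10/18/2021" be?
Output: 2021-10-18

Input: If today was 2041-03-20, what would the date of "3 weeks ago" be?
Output: 2041-02-27

Input: If today was 2055-12-01, what would the date of "July 2055" be?
Output: 2055-07

Input: If today was 2027-06-15, what would the date of "some future visit" be?
Output: Unknown
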